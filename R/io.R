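#' Read a binary fingerprint matrix
#'
#' Reads a drug-by-feature binary profile matrix (chemical substructure
#' fingerprints or side-effect annotations) from a tab-separated file with a
#' header row of feature identifiers and a first column of drug identifiers.
#' Row and column order is preserved from the file so downstream similarity
#' matrices are reproducible.
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @return An integer matrix with drugs as rows and features as columns;
#'   entries are 0/1 (1 = feature present).
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fmt("fingerprint file '%s' needs >= 1 feature column", path)
  drugs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- drugs
  validate_fingerprints(m, what = path)
  storage.mode(m) <- "integer"
  m
}

validate_fingerprints <- function(m, what = "fingerprint matrix") {
  if (anyDuplicated(rownames(m))) {
    stop_fmt("%s: duplicate drug ids (%s)", what,
             paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop_fmt("%s: duplicate feature ids (%s)", what,
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop_fmt("%s: non-binary value '%s' at drug '%s', feature '%s'",
             what, format(m[i, j]), rownames(m)[i], colnames(m)[j])
  }
  invisible(m)
}

#' Write a binary fingerprint matrix
#'
#' @param m Integer 0/1 matrix with drug row names and feature column names.
#' @param path Output TSV path.
#' @export
write_fingerprints <- function(m, path) {
  validate_fingerprints(m)
  df <- data.frame(drug_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drug-disease association tables
#'
#' An association table holds the gold-standard positive edges of the
#' bipartite drug-disease graph, together with the drug and disease label
#' universes (which may include isolated entities).
#'
#' @param edges Data frame (or 2-column matrix) of drug, disease pairs.
#' @param drugs,diseases Optional label universes; default to observed labels.
#' @return An object of class `association_table` with elements `edges`
#'   (de-duplicated data frame with columns drug, disease), `drugs`, `diseases`.
#' @export
association_table <- function(edges, drugs = NULL, diseases = NULL) {
  edges <- pair_frame(edges[[1L]], edges[[2L]])
  edges <- edges[!duplicated(pair_key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  drugs <- as.character(drugs %||% unique(edges$drug))
  diseases <- as.character(diseases %||% unique(edges$disease))
  if (!all(edges$drug %in% drugs)) {
    stop_fmt("edge drugs outside universe: %s",
             paste(setdiff(edges$drug, drugs), collapse = ", "))
  }
  if (!all(edges$disease %in% diseases)) {
    stop_fmt("edge diseases outside universe: %s",
             paste(setdiff(edges$disease, diseases), collapse = ", "))
  }
  structure(list(edges = edges, drugs = drugs, diseases = diseases),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Drug-disease association table: %d edges, %d drugs, %d diseases\n",
              nrow(x$edges), length(x$drugs), length(x$diseases)))
  invisible(x)
}

#' Read a drug-disease association edge list
#'
#' @param path Two-column TSV (drug_id, disease_id); `#` lines are comments.
#' @param drugs,diseases Optional explicit label universes.
#' @return An [association_table()].
#' @export
read_associations <- function(path, drugs = NULL, diseases = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop_fmt("association file '%s' is empty", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop_fmt("association file '%s': malformed line %d (expected 2 tab-separated fields)",
             path, which(keep)[which(nf != 2L)[1L]])
  }
  edges <- pair_frame(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
  association_table(edges, drugs = drugs, diseases = diseases)
}

#' Write a drug-disease association edge list
#'
#' @param a An [association_table()].
#' @param path Output TSV path.
#' @export
write_associations <- function(a, path) {
  stopifnot(inherits(a, "association_table"))
  utils::write.table(a$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a square similarity matrix
#'
#' Checks the matrix is square, labeled, finite and symmetric (to `tol`);
#' asymmetry within `tol` is repaired by averaging with the transpose.
#'
#' @param m Numeric matrix with matching row/column names.
#' @param tol Largest tolerated absolute asymmetry (default 1e-10; readers use
#'   a looser 1e-6 to absorb text-format rounding).
#' @return The validated (symmetrized) matrix.
#' @export
as_similarity_matrix <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_fmt("similarity matrix must be square (%d x %d)", nrow(m), ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) stop_fmt("similarity matrix must be labeled")
  if (!identical(rownames(m), colnames(m))) stop_fmt("row and column labels differ")
  if (anyDuplicated(rownames(m))) stop_fmt("duplicate similarity-matrix ids")
  if (!all(is.finite(m))) stop_fmt("similarity matrix has non-finite entries")
  asym <- max_asymmetry(m)
  if (asym > tol) stop_fmt("similarity matrix asymmetric beyond tolerance (%.3g > %.3g)", asym, tol)
  (m + t(m)) / 2
}

#' Read a similarity matrix
#'
#' Reads a square labeled similarity matrix (e.g. a phenotype similarity
#' matrix) from TSV with a header row and first-column labels. Asymmetry up to
#' 1e-6 is repaired by averaging; larger asymmetry is an error.
#'
#' @param path Path to the TSV file.
#' @return A symmetric numeric matrix.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m))) {
    stop_fmt("similarity file '%s': header and first-column labels differ", path)
  }
  as_similarity_matrix(m, tol = 1e-6)
}

#' Write a similarity matrix
#'
#' Real values are written with `%.6g` precision.
#'
#' @param m Symmetric labeled numeric matrix.
#' @param path Output TSV path.
#' @export
write_similarity_matrix <- function(m, path) {
  m <- as_similarity_matrix(m, tol = 1e-10)
  body <- apply(m, 1L, function(r) paste(sprintf("%.6g", r), collapse = "\t"))
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-to-target map with protein sequences
#'
#' @param map_path Two-column TSV (drug_id, protein_id).
#' @param fasta_path FASTA file whose ids cover every protein in the map.
#' @return A list with `targets` (named list: drug id -> character vector of
#'   protein ids) and `sequences` (named character vector of amino-acid
#'   sequences).
#' @export
read_target_data <- function(map_path, fasta_path) {
  a <- read_associations(map_path)  # same 2-column TSV dialect
  targets <- split(a$edges$disease, factor(a$edges$drug, levels = unique(a$edges$drug)))
  targets <- lapply(targets, unique)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  sequences <- as.character(seqs)
  names(sequences) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(sequences))) stop_fmt("duplicate FASTA ids in '%s'", fasta_path)
  missing <- setdiff(unique(unlist(targets)), names(sequences))
  if (length(missing)) {
    stop_fmt("proteins in target map missing from FASTA: %s",
             paste(missing, collapse = ", "))
  }
  validate_sequences(sequences)
  list(targets = targets, sequences = sequences)
}

validate_sequences <- function(sequences) {
  if (!length(sequences)) stop_fmt("empty sequence store")
  if (any(!nzchar(sequences))) stop_fmt("empty sequence for id(s): %s",
                                        paste(names(sequences)[!nzchar(sequences)], collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequences)
  if (any(bad)) stop_fmt("non-standard residues in sequence(s): %s",
                         paste(names(sequences)[bad], collapse = ", "))
  invisible(sequences)
}

#' Write target map and sequences
#'
#' @param targets Named list: drug id -> character vector of protein ids.
#' @param sequences Named character vector of amino-acid sequences.
#' @param map_path,fasta_path Output paths.
#' @export
write_target_data <- function(targets, sequences, map_path, fasta_path) {
  edges <- data.frame(
    drug = rep(names(targets), lengths(targets)),
    protein = unlist(targets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(edges, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, fasta_path)
  invisible(map_path)
}
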