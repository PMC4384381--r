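#' Read a 2-column annotation TSV
#'
#' Lines are `protein<TAB>label`; `#` comment lines are skipped and duplicate
#' rows collapse silently. Identifiers are case-sensitive opaque strings.
#'
#' @param path file path.
#' @return data.frame with columns `protein`, `label`.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  df <- unique(df[, 1:2])
  names(df) <- c("protein", "label")
  rownames(df) <- NULL
  df
}

#' Write closed annotations as a 2-column TSV
#' @param Y binary annotation matrix.
#' @param path output file path.
#' @export
write_annotations_tsv <- function(Y, path) {
  idx <- which(Y == 1, arr.ind = TRUE)
  df <- data.frame(protein = rownames(Y)[idx[, 1]],
                   label = colnames(Y)[idx[, 2]])
  df <- df[order(df$protein, df$label), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column weighted edge TSV
#' @param path file path (`protein_a<TAB>protein_b<TAB>weight`, `#` comments
#'   allowed).
#' @return data.frame with columns `protein_a`, `protein_b`, `weight`.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("protein_a", "protein_b", "weight")
  df
}

#' Read protein-term pairs from a GAF 2.x file
#'
#' Keeps columns 2 (DB object ID) and 5 (GO ID); rows whose evidence code
#' (column 7) is in `exclude_evidence` are dropped. Comment lines start with
#' `!`.
#'
#' @param path GAF file path.
#' @param exclude_evidence character vector of evidence codes to drop
#'   (default `"IEA"`).
#' @return data.frame with columns `protein`, `label`.
#' @export
read_gaf <- function(path, exclude_evidence = "IEA") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(data.frame(protein = character(0),
                                        label = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p)
    length(p) >= 7 && !(p[[7]] %in% exclude_evidence), logical(1))
  parts <- parts[keep]
  unique(data.frame(protein = vapply(parts, `[[`, character(1), 2),
                    label = vapply(parts, `[[`, character(1), 5)))
}

#' Build an annotation matrix from (protein, label) pairs and a hierarchy
#'
#' Drops pairs whose label is absent from the hierarchy (with a message),
#' then applies the true path closure.
#'
#' @param pairs data.frame with columns protein, label.
#' @param h a `label_hierarchy`.
#' @param proteins optional ordered protein universe (defaults to the
#'   proteins seen, in order of first appearance).
#' @return Closed binary annotation matrix.
#' @export
annotation_matrix <- function(pairs, h, proteins = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  known <- pairs[[2]] %in% h$labels
  if (any(!known)) {
    message(sum(!known), " annotation(s) with labels absent from the ",
            "hierarchy dropped")
    pairs <- pairs[known, , drop = FALSE]
  }
  if (is.null(proteins)) proteins <- unique(as.character(pairs[[1]]))
  Y <- matrix(0, length(proteins), length(h$labels),
              dimnames = list(proteins, h$labels))
  if (nrow(pairs)) Y[cbind(as.character(pairs[[1]]),
                           as.character(pairs[[2]]))] <- 1
  true_path_closure(Y, h)
}
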