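#' Write a data frame as TSV
#' @param x data.frame
#' @param path output file
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path input file
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a numeric matrix as TSV with a leading id column
#' @param m matrix with dimnames
#' @param path output file
#' @param id_col name for the row-id column
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path input file
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects
#' (Hubert & Arabie correction). Used to compare a recovered module
#' partition with the planted one.
#'
#' @param a,b Label vectors of equal length (any type coercible to factor).
#' @return ARI in \[-1, 1\]; 1 is perfect agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
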