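# Genotype container: individuals x markers allele-count codes plus an
# optional marker map. Codes count copies of the alternative allele.

#' Construct a genotype matrix
#'
#' The universal carrier between pipeline stages: a numeric matrix of
#' alternative-allele counts (rows = individuals, columns = markers) with an
#' optional marker map giving chromosome and 1-based physical position.
#'
#' @param codes numeric matrix with entries in \{0, 1, 2\} or `NA`; must have
#'   unique row names (individual ids) and column names (marker ids).
#' @param map optional `data.frame` with columns `marker`, `chrom`, `pos`
#'   (1-based bp). Reordered to match `colnames(codes)`.
#' @return an object of class `geno_matrix`: a list with elements `codes`
#'   and `map` (possibly `NULL`).
#' @export
geno_matrix <- function(codes, map = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (nrow(codes) > 0 &&
      (is.null(rownames(codes)) || anyDuplicated(rownames(codes))))
    stop("individual ids (rownames) must be present and unique")
  if (ncol(codes) > 0 &&
      (is.null(colnames(codes)) || anyDuplicated(colnames(codes))))
    stop("marker ids (colnames) must be present and unique")
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or missing; found ",
         paste(unique(codes[bad])[seq_len(min(3, sum(bad)))], collapse = ", "))
  if (!is.null(map)) {
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(map)))
      stop("marker map needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(map$marker)) stop("duplicated marker id in map")
    if (!all(colnames(codes) %in% map$marker))
      stop("marker map does not cover all markers")
    map <- map[match(colnames(codes), map$marker), need, drop = FALSE]
    rownames(map) <- NULL
  }
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%s map, %.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              if (is.null(x$map)) "no" else "with",
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Individual and marker ids of a genotype matrix
#' @param G a `geno_matrix`.
#' @return character vector of ids.
#' @export
individual_ids <- function(G) rownames(G$codes)

#' @rdname individual_ids
#' @export
marker_ids <- function(G) colnames(G$codes)

#' Subset a genotype matrix by individuals and/or markers
#' @param G a `geno_matrix`.
#' @param individuals,markers character, integer or logical index; `NULL`
#'   keeps everything.
#' @return a `geno_matrix`.
#' @export
gm_subset <- function(G, individuals = NULL, markers = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  codes <- G$codes
  if (!is.null(individuals)) {
    if (is.character(individuals) && !all(individuals %in% rownames(codes)))
      stop("unknown individual id(s): ",
           paste(setdiff(individuals, rownames(codes))[1:3], collapse = ", "))
    codes <- codes[individuals, , drop = FALSE]
  }
  if (!is.null(markers)) {
    if (is.character(markers) && !all(markers %in% colnames(codes)))
      stop("unknown marker id(s)")
    codes <- codes[, markers, drop = FALSE]
  }
  map <- G$map
  if (!is.null(map)) map <- map[map$marker %in% colnames(codes), , drop = FALSE]
  geno_matrix(codes, map)
}

#' Stack two genotype matrices over the same marker panel
#' @param A,B `geno_matrix` objects with identical marker sets (same order).
#' @return a `geno_matrix` containing the rows of both.
#' @export
gm_rbind <- function(A, B) {
  stopifnot(inherits(A, "geno_matrix"), inherits(B, "geno_matrix"))
  if (!identical(colnames(A$codes), colnames(B$codes)))
    stop("marker sets differ; align panels before stacking")
  if (any(rownames(B$codes) %in% rownames(A$codes)))
    stop("duplicated individual ids across the two matrices")
  geno_matrix(rbind(A$codes, B$codes), A$map)
}

# allele frequency of the alternative allele, per marker (missing ignored)
alt_freq <- function(codes) colMeans(codes, na.rm = TRUE) / 2

# minor allele frequency per marker
maf_of <- function(codes) {
  p <- alt_freq(codes)
  pmin(p, 1 - p)
}
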