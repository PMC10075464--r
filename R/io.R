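# Delimited-text file formats binding the pipeline together.
# Canonical formats are TSV; missing genotype code token is "NA".

#' Read a genotype matrix
#'
#' Two dialects: `matrix_tsv` — a TSV with the individual id in the first
#' column and one column per marker (header = marker ids), codes 0/1/2/NA —
#' and `plink_ped_map` — PLINK-style .ped/.map files, codes counted against
#' a declared alternative allele (default: the minor allele; ties broken
#' lexicographically).
#'
#' @param path genotype file (.ped for the PLINK dialect).
#' @param dialect `"matrix_tsv"` or `"plink_ped_map"`.
#' @param map_path optional marker-map TSV (columns marker, chrom, pos) for
#'   the matrix dialect; the .map file for the PLINK dialect (defaults to
#'   `path` with extension swapped).
#' @param alt_alleles optional named character vector (marker -> alternative
#'   allele) for the PLINK dialect.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("matrix_tsv", "plink_ped_map"),
                           map_path = NULL, alt_alleles = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix_tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicated individual id in ", path)
    hdr <- colnames(df)[-1]  # check before [-1] subsetting mangles dup names
    if (anyDuplicated(hdr))
      stop("duplicated marker id: ", hdr[anyDuplicated(hdr)])
    codes <- as.matrix(df[-1])
    colnames(codes) <- hdr
    suppressWarnings(storage.mode(codes) <- "double")
    bad <- which(!(codes %in% c(0, 1, 2) | is.na(codes)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("unknown genotype code at row %d, marker '%s'",
                   bad[1, 1], colnames(codes)[bad[1, 2]]))
    rownames(codes) <- ids
    map <- if (!is.null(map_path))
      read.table(map_path, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
    geno_matrix(codes, map)
  } else {
    if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
    mp <- read.table(map_path, header = FALSE, sep = "",
                     stringsAsFactors = FALSE)
    if (ncol(mp) < 4) stop("PLINK .map needs 4 columns")
    map <- data.frame(marker = as.character(mp[[2]]), chrom = mp[[1]],
                      pos = as.integer(mp[[4]]), stringsAsFactors = FALSE)
    if (anyDuplicated(map$marker))
      stop("duplicated marker id: ", map$marker[anyDuplicated(map$marker)])
    ped <- read.table(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE, colClasses = "character")
    m <- nrow(map)
    if (ncol(ped) != 6 + 2 * m)
      stop(".ped column count does not match the .map marker count")
    ids <- ped[[2]]
    if (anyDuplicated(ids)) stop("duplicated individual id in ", path)
    a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1])
    a2 <- as.matrix(ped[, 6 + 2 * seq_len(m)])
    codes <- matrix(NA_real_, length(ids), m,
                    dimnames = list(ids, map$marker))
    for (j in seq_len(m)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[!obs %in% c("0", "-", "N")]
      alleles <- sort(unique(obs))
      if (length(alleles) > 2) stop("marker ", map$marker[j], " is multi-allelic")
      alt <- if (!is.null(alt_alleles) && map$marker[j] %in% names(alt_alleles)) {
        alt_alleles[[map$marker[j]]]
      } else if (length(alleles) <= 1) {
        alleles[1]
      } else {
        cnt <- table(factor(obs, levels = alleles))
        if (cnt[1] == cnt[2]) alleles[2] else names(cnt)[which.min(cnt)]
      }
      miss <- a1[, j] %in% c("0", "-", "N") | a2[, j] %in% c("0", "-", "N")
      codes[, j] <- (a1[, j] == alt) + (a2[, j] == alt)
      codes[miss, j] <- NA
    }
    geno_matrix(codes, map)
  }
}

#' Write a genotype matrix as TSV
#'
#' @param G a `geno_matrix`.
#' @param path output TSV; the first column is `id`.
#' @param map_path optional path for the marker map TSV.
#' @export
write_genotypes <- function(G, path, map_path = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  df <- data.frame(id = rownames(G$codes), G$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path) && !is.null(G$map))
    write.table(G$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read replicated phenotype records
#'
#' @param path TSV with header genotype_id, block, value.
#' @return data.frame of records.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("genotype_id", "block", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  df$value <- as.numeric(df$value)
  df
}

#' Read a pedigree map
#'
#' @param path TSV with header hybrid, female, male.
#' @return data.frame pedigree.
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("hybrid", "female", "male")
  if (!all(need %in% names(df)))
    stop("pedigree file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$hybrid)) stop("duplicated hybrid id in pedigree")
  df
}

#' Read/write a BLUE table
#'
#' @param x named numeric BLUEs (write) / `path` TSV (read).
#' @param path file path.
#' @return named numeric vector (read) or the path, invisibly (write).
#' @export
write_blue <- function(x, path) {
  write.table(data.frame(genotype_id = names(x), blue = unname(x)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blue
#' @export
read_blue <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(df$blue, df$genotype_id)
}

#' Write a heterosis table (S4-style columns)
#' @param het a [compute_heterosis()] result.
#' @param path output TSV.
#' @export
write_heterosis <- function(het, path) {
  write.table(het, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cross-validation results
#' @param res a `cv_result` (or rbind of several).
#' @param path output TSV.
#' @export
write_cv_results <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# tiny stable content hash (polynomial rolling, 31-bit) for run manifests
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration hash, seeds and package version so a run can
#' be reproduced bit-identically.
#'
#' @param config named list of run settings.
#' @param path output file (JSON-style text).
#' @export
write_manifest <- function(config, path) {
  config$config_hash <- content_hash(utils::capture.output(utils::str(config)))
  config$package_version <- as.character(utils::packageVersion("halfsibGP"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
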