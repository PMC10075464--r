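# Shared fixtures, built in code once per test run.

.fx <- new.env()

# small complete half-sib trial with BLUEs and CV bundle
fx_trial <- function() {
  if (is.null(.fx$trial)) {
    tr <- simulate_halfsib_trial(
      n_lines = 60, n_markers = 300,
      arch = trait_architecture(n_qtl = 40, target_h2 = 0.6),
      seed = 42)
    tr$blue <- compute_blue(tr$records)
    tr$data <- cv_data(tr$parents, tr$hybrids, tr$pedigree, tr$blue)
    .fx$trial <- tr
  }
  .fx$trial
}

# a hand-buildable genotype matrix
fx_geno <- function(codes, chrom = NULL, pos = NULL) {
  if (is.null(rownames(codes))) rownames(codes) <- paste0("i", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("m", seq_len(ncol(codes)))
  map <- NULL
  if (!is.null(chrom))
    map <- data.frame(marker = colnames(codes), chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE)
  geno_matrix(codes, map)
}

# full-size (402 lines / 401 hybrids) id-only pedigree for composition tests
fx_pedigree_402 <- function() {
  lines <- sprintf("L%04d", 1:402)
  data.frame(hybrid = paste0("H.", lines[-1]), female = lines[1],
             male = lines[-1], stringsAsFactors = FALSE)
}
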