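# Phenotype adjustment (RCBD fixed-effects BLUEs) and heterosis statistics.

#' Adjust replicated phenotypes to per-genotype BLUEs
#'
#' Fits the two-way fixed-effects model value = genotype + block + error with
#' a sum-to-zero constraint on blocks, and returns each genotype's estimated
#' mean on the observation scale (intercept absorbed into the genotype
#' effect). For a balanced complete block design this equals the genotype's
#' raw mean across blocks; for unbalanced data it is the ordinary
#' least-squares solution of the full two-way model.
#'
#' @param records data.frame with columns `genotype_id`, `block`, `value`;
#'   no duplicated (genotype, block) pair, at least one record per genotype.
#' @return named numeric vector of BLUEs, one per genotype, in first-seen
#'   genotype order.
#' @export
compute_blue <- function(records) {
  need <- c("genotype_id", "block", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(records[c("genotype_id", "block")]))
    stop("duplicated (genotype_id, block) pair in records")
  if (any(!is.finite(records$value))) stop("non-finite phenotype value")
  gid <- factor(records$genotype_id, levels = unique(records$genotype_id))
  blk <- factor(records$block)
  ng <- nlevels(gid); nb <- nlevels(blk)
  # genotype indicators (no intercept) + sum-to-zero block columns
  Xg <- matrix(0, nrow(records), ng)
  Xg[cbind(seq_len(nrow(records)), as.integer(gid))] <- 1
  if (nb > 1) {
    Cb <- stats::contr.sum(nb)
    Xb <- Cb[as.integer(blk), , drop = FALSE]
    X <- cbind(Xg, Xb)
  } else X <- Xg
  fit <- lm.fit(X, records$value)
  if (fit$rank < ncol(X))
    stop("design is rank deficient beyond the block constraint; ",
         "genotype means are not estimable")
  setNames(fit$coefficients[seq_len(ng)], levels(gid))
}

#' Heterosis statistic and classification per hybrid
#'
#' Computes Hp = 2 (F1 - MP) / |P1 - P2| from hybrid and parental BLUEs,
#' where MP = (P1 + P2) / 2, P1 is the male and P2 the female parent value.
#' Classes: Hp > 1 high-parent heterosis (HPH); 0 <= Hp <= 1 mid-parent
#' heterosis (MPH); -1 <= Hp < 0 low-parent heterosis (LPH); Hp < -1 hybrid
#' inferiority (HI). Hp = 0 (F1 exactly at the mid-parent) is grouped with
#' MPH. Hybrids with P1 = P2 have undefined Hp; they are flagged and
#' excluded from the class proportions.
#'
#' @param blue named numeric vector of BLUEs (from [compute_blue()]).
#' @param pedigree data.frame with columns `hybrid`, `female`, `male`.
#' @param tol absolute tolerance below which |P1 - P2| counts as zero.
#' @return data.frame with columns hybrid_id, f1, mp, p1, p2, d_value
#'   (F1 - MP), a_value (|P1 - P2|), hp, hclass (NA when undefined); class
#'   proportions over classifiable hybrids in attribute `"proportions"`.
#' @export
compute_heterosis <- function(blue, pedigree, tol = 1e-12) {
  need <- c("hybrid", "female", "male")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  ids <- unique(c(pedigree$hybrid, pedigree$female, pedigree$male))
  miss <- setdiff(ids, names(blue))
  if (length(miss))
    stop("BLUEs missing for: ", paste(head(miss, 3), collapse = ", "))
  f1 <- unname(blue[pedigree$hybrid])
  p1 <- unname(blue[pedigree$male])    # male parent
  p2 <- unname(blue[pedigree$female])  # female parent
  mp <- (p1 + p2) / 2
  a_value <- abs(p1 - p2)
  d_value <- f1 - mp
  hp <- ifelse(a_value > tol, 2 * d_value / a_value, NA_real_)
  hclass <- rep(NA_character_, length(hp))
  ok <- !is.na(hp)
  hclass[ok & hp > 1] <- "HPH"
  hclass[ok & hp >= 0 & hp <= 1] <- "MPH"
  hclass[ok & hp < 0 & hp >= -1] <- "LPH"
  hclass[ok & hp < -1] <- "HI"
  out <- data.frame(hybrid_id = pedigree$hybrid, f1 = f1, mp = mp, p1 = p1,
                    p2 = p2, d_value = d_value, a_value = a_value, hp = hp,
                    hclass = hclass, stringsAsFactors = FALSE)
  tab <- table(factor(hclass[ok], levels = c("HPH", "MPH", "LPH", "HI")))
  attr(out, "proportions") <-
    if (sum(tab) > 0) as.numeric(tab) / sum(tab) else rep(NA_real_, 4)
  names(attr(out, "proportions")) <- c("HPH", "MPH", "LPH", "HI")
  out
}
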