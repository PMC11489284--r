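# Small hand-built fixtures used across the suite.

comp_row <- function(treatment = "aCO2", array_id = "a1",
                     tree_id = paste0("tree_", array_id),
                     subsample_id = "s1", element = "C",
                     concentration = 49.7, unit = "percent_dry_mass") {
  data.frame(treatment = treatment, array_id = array_id, tree_id = tree_id,
             subsample_id = subsample_id, element = element,
             concentration = concentration, unit = unit,
             stringsAsFactors = FALSE)
}

# one treatment pair, one array each, C+N on a single subsample
tiny_cn_table <- function(c_a = 50, n_a = 5, c_e = 50, n_e = 5) {
  composition_table(rbind(
    comp_row("aCO2", "a1", subsample_id = "a1_s1", element = "C",
             concentration = c_a),
    comp_row("aCO2", "a1", subsample_id = "a1_s1", element = "N",
             concentration = n_a),
    comp_row("eCO2", "e1", subsample_id = "e1_s1", element = "C",
             concentration = c_e),
    comp_row("eCO2", "e1", subsample_id = "e1_s1", element = "N",
             concentration = n_e)))
}

# sort-and-interpolate quantile oracle (independent of stats::quantile)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force PERMANOVA: enumerate label assignments with explicit loops
permanova_oracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  a <- length(unique(labels))
  ss_tot <- sum(d[lower.tri(d)]^2) / n
  f_of <- function(lab) {
    ssw <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      s <- 0
      if (length(idx) > 1) {
        for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
      }
      ssw <- ssw + s / length(idx)
    }
    if (ssw <= 0) return(Inf)
    ((ss_tot - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(labels)
  perms <- rbind(seq_len(n))
  for (k in 2:n) {
    grown <- list()
    for (r in seq_len(nrow(perms))) {
      for (pos in 0:(k - 1)) {
        grown[[length(grown) + 1]] <- append(perms[r, seq_len(k - 1)], k,
                                             after = pos)
      }
    }
    perms <- do.call(rbind, grown)
  }
  f_all <- apply(perms, 1, function(idx) f_of(labels[idx]))
  list(f = f_obs,
       p = mean(f_all >= f_obs - 1e-12 * max(1, abs(f_obs))))
}
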