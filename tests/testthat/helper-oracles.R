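# Independent oracles and small fixtures shared across test files.

# Brute-force D_RS: explicit double loop over (resected, spared) pairs.
drs_brute <- function(scores, resected) {
  r <- scores[resected]
  s <- scores[!resected]
  tot <- 0
  for (a in r) for (b in s) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(r) * length(s))
}

# Brute-force constrained tree: independent enumeration of every
# (root modality, root cut, child, second cut) with if/else prediction;
# returns the best training accuracy only.
tree_brute_accuracy <- function(ieeg, conn, good) {
  mids <- function(x) {
    u <- sort(unique(x))
    (u[-1] + u[-length(u)]) / 2
  }
  maj <- function(g) if (sum(g) >= sum(!g)) TRUE else FALSE
  best <- 0
  for (root in c("i", "c")) {
    rv <- if (root == "i") ieeg else conn
    sv <- if (root == "i") conn else ieeg
    for (t1 in mids(rv)) for (child in c("lo", "hi")) {
      inside <- if (child == "lo") rv <= t1 else rv > t1
      if (!any(inside) || all(inside)) next
      for (t2 in mids(sv)) {
        pred <- logical(length(good))
        pred[!inside] <- maj(good[!inside])
        a <- inside & sv <= t2
        b <- inside & sv > t2
        if (any(a)) pred[a] <- maj(good[a])
        if (any(b)) pred[b] <- maj(good[b])
        best <- max(best, mean(pred == good))
      }
    }
  }
  best
}

# compact cohort configs used throughout
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_controls = 24, n_patients = 6, n_regions = 20,
                   n_sites = 2, n_ieeg_normative = 8,
                   coverage_fraction = 0.3, fs = 256, seed = 11)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

subject_info <- function(subjects) {
  data.frame(site = vapply(subjects, function(s) s$site, numeric(1)),
             age = vapply(subjects, function(s) s$age, numeric(1)),
             sex = vapply(subjects, function(s) s$sex, character(1)),
             stringsAsFactors = FALSE)
}
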