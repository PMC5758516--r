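# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (pair enumeration, direct
# formulas) without touching the package's computational paths.

# small phantom configuration used by most image-level tests
small_config <- function(seed = 1, n_studies = 6L, n_train = 4L,
                         shape = c(32L, 32L, 10L)) {
  cohort_config(n_studies = n_studies, n_train = n_train,
                volume_shape = shape, seed = seed)
}

# per-pixel Haralick oracle: enumerate every in-window, in-mask pixel pair,
# build the GLCM as a plain matrix and evaluate the 13 statistics directly
oracle_haralick <- function(q, mask, nlev, radius, offsets, symmetric) {
  nr <- nrow(q); nc <- ncol(q)
  out <- array(NA_real_, c(nr, nc, 13))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    r0 <- max(1, i - radius); r1 <- min(nr, i + radius)
    c0 <- max(1, j - radius); c1 <- min(nc, j + radius)
    P <- matrix(0, nlev, nlev)
    for (b in c0:c1) for (a in r0:r1) {
      if (!mask[a, b]) next
      for (o in seq_len(nrow(offsets))) {
        a2 <- a + offsets[o, 1]; b2 <- b + offsets[o, 2]
        if (a2 < r0 || a2 > r1 || b2 < c0 || b2 > c1) next
        if (!mask[a2, b2]) next
        P[q[a, b] + 1, q[a2, b2] + 1] <- P[q[a, b] + 1, q[a2, b2] + 1] + 1
        if (symmetric)
          P[q[a2, b2] + 1, q[a, b] + 1] <- P[q[a2, b2] + 1, q[a, b] + 1] + 1
      }
    }
    if (sum(P) == 0) next
    out[i, j, ] <- oracle_haralick_stats(P / sum(P))
  }
  out
}

# the 13 statistics from a normalized GLCM, by their textbook formulas
oracle_haralick_stats <- function(P) {
  nlev <- nrow(P)
  lv <- seq_len(nlev)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  ii <- matrix(lv, nlev, nlev); jj <- t(ii)
  nz <- P > 0
  ent <- -sum(P[nz] * log(P[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  pp <- outer(px, py)
  hxy1 <- -sum(P[nz] * log(pp[nz]))
  hxy2 <- -sum(pp[pp > 0] * log(pp[pp > 0]))
  ks <- 2:(2 * nlev)
  pxy <- vapply(ks, function(k) sum(P[ii + jj == k]), numeric(1))
  ds <- 0:(nlev - 1)
  pmd <- vapply(ds, function(d) sum(P[abs(ii - jj) == d]), numeric(1))
  sa <- sum(ks * pxy)
  dm <- sum(ds * pmd)
  c(energy = sum(P^2),
    contrast = sum((ii - jj)^2 * P),
    correlation = if (sx * sy > 1e-12) (sum(ii * jj * P) - mux * muy) / (sx * sy) else 0,
    variance = sum((ii - mux)^2 * P),
    idm = sum(P / (1 + (ii - jj)^2)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * pxy),
    sum_entropy = -sum(pxy[pxy > 0] * log(pxy[pxy > 0])),
    entropy = ent,
    difference_variance = sum((ds - dm)^2 * pmd),
    difference_entropy = -sum(pmd[pmd > 0] * log(pmd[pmd > 0])),
    imc1 = if (max(hx, hy) > 1e-12) (ent - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))))
}

# ssGSEA oracle: literal step-by-step walk of the ranked list
oracle_ssgsea <- function(profile, gene_set, alpha) {
  ord <- order(-profile, names(profile))
  x <- profile[ord]
  inset <- names(x) %in% gene_set
  w <- abs(x)^alpha
  w[!inset] <- 0
  if (sum(w) == 0) w[inset] <- 1 / sum(inset) else w <- w / sum(w)
  es <- 0; p_hit <- 0; p_miss <- 0
  for (i in seq_along(x)) {
    if (inset[i]) p_hit <- p_hit + w[i] else p_miss <- p_miss + 1 / sum(!inset)
    es <- es + (p_hit - p_miss)
  }
  unname(es)
}

# Harrell's C by O(n^2) pair enumeration (ties in risk count one half;
# a pair is comparable when the earlier time is an observed event and the
# times differ)
oracle_concordance <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (event[first] == 0) next
    comp <- comp + 1
    if (risk[first] > risk[other]) conc <- conc + 1
    else if (risk[first] == risk[other]) conc <- conc + 0.5
  }
  conc / comp
}

# plug-in MI recomputed through the entropy identity H(X) + H(Y) - H(X, Y)
oracle_mi <- function(xb, y) {
  tab <- table(xb, y)
  p <- tab / sum(tab)
  hx <- -sum(rowSums(p)[rowSums(p) > 0] * log(rowSums(p)[rowSums(p) > 0]))
  hy <- -sum(colSums(p)[colSums(p) > 0] * log(colSums(p)[colSums(p) > 0]))
  hxy <- -sum(p[p > 0] * log(p[p > 0]))
  hx + hy - hxy
}
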