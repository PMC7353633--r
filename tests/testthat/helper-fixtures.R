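# Shared fixtures and small generators for the test suite.

t1 <- load_table1_fixture()
t3 <- load_table3_fixture()
registry <- load_adulterant_registry()

# a small random but physically plausible composition table
random_table <- function(n, seed) {
  withr::with_seed(seed, {
    fat <- rnorm(n, 3.95, 0.2)
    snf <- rnorm(n, 9.33, 0.3)
    data.frame(
      sample_id = paste0("R", seq_len(n)),
      protein = rnorm(n, 3.54, 0.15),
      fat = fat,
      ts = fat + snf + rnorm(n, 0, 0.05),
      snf = snf,
      lactose = rnorm(n, 5.06, 0.2),
      density = rnorm(n, 1032, 1.2),
      fpd = rnorm(n, 0.543, 0.02),
      stringsAsFactors = FALSE
    )
  })
}

# independent percentile oracle: sort and linearly interpolate order stats
oracle_percentile <- function(x, pct) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * pct / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# independent PCR leave-one-out oracle: eigen() components + lm() per fold
oracle_press <- function(X, y, a) {
  n <- nrow(X)
  sum(vapply(seq_len(n), function(i) {
    Xf <- X[-i, , drop = FALSE]
    yf <- y[-i]
    ctr <- colMeans(Xf)
    scl <- apply(Xf, 2, sd)
    keep <- scl > 1e-12
    Xs <- scale(Xf[, keep, drop = FALSE], ctr[keep], scl[keep])
    ev <- eigen(cov(Xs), symmetric = TRUE)
    rank <- sum(ev$values > max(ev$values) * 1e-10)
    V <- ev$vectors[, seq_len(min(a, rank)), drop = FALSE]
    Tm <- Xs %*% V
    fit <- lm(yf ~ Tm)
    xs <- (X[i, keep] - ctr[keep]) / scl[keep]
    pred <- sum(coef(fit) * c(1, as.numeric(xs %*% V)))
    (y[i] - pred)^2
  }, 0))
}

# independent two-component mixing oracle for adulteration mass balance
oracle_mix <- function(base, spec, added, water_added, milk_mass = 100) {
  total <- milk_mass + water_added + added
  comp <- function(pct) pct * milk_mass / 100
  list(
    protein = (comp(base$protein) +
                 added * (spec$protein_fraction + 6.38 * spec$nitrogen_fraction)) /
      total * 100,
    fat = comp(base$fat) / total * 100,
    ts = (comp(base$ts) + added * spec$solids_fraction) / total * 100,
    snf = (comp(base$snf) + added * spec$solids_fraction) / total * 100,
    lactose = (comp(base$lactose) +
                 if (spec$category == "carbohydrate") added * spec$solids_fraction else 0) /
      total * 100
  )
}
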