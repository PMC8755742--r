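test_that("bicor has the correlation identities and tracks Pearson", {
  set.seed(21)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  ## outlier-free Gaussian pairs: bicor close to Pearson
  d <- vapply(1:500, function(i) {
    a <- rnorm(100); b <- 0.5 * a + rnorm(100)
    abs(bicor(a, b) - cor(a, b))
  }, numeric(1))
  expect_gte(mean(d < 0.05), 0.95)
  expect_gte(mean(d < 0.10), 0.99)
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(22)
  wins <- vapply(1:50, function(i) {
    a <- rnorm(40); b <- 0.8 * a + 0.6 * rnorm(40)
    clean <- cor(a, b)
    a_c <- a; a_c[1] <- 15  # gross contamination
    abs(bicor(a_c, b) - clean) < abs(cor(a_c, b) - clean)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("zero-MAD profiles fall back to mean-centering (Pearson)", {
  ## both vectors degenerate: exact Pearson
  x <- c(rep(1, 10), 5, 6)  # MAD 0, nonconstant
  y <- c(rep(2, 9), 7, 8, 9)
  expect_equal(bicor(x, y), cor(x, y), tolerance = 1e-12)
  ## one degenerate vector: its side is mean-centered, the other keeps
  ## its biweights, so the value stays close to Pearson
  yn <- seq_len(12)
  expect_lt(abs(bicor(x, yn) - cor(x, yn)), 0.05)
  expect_error(bicor_matrix(matrix(1, 3, 2)), "at least 4 samples")
})

test_that("signed adjacency follows ((1 + rho)/2)^beta", {
  rho <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3)
  a <- signed_adjacency(rho, beta = 22)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 2], 0.5^22)
  expect_equal(a[2, 3], 0.75^22)
  expect_true(all(diag(a) == 1))
  ## strictly increasing in rho
  r <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(((1 + r) / 2)^22) > 0))
  expect_error(signed_adjacency(rho, beta = 0.5), "beta")
  expect_error(signed_adjacency(rho * 2), "\\[-1, 1\\]")
})

test_that("topological overlap matches the 3-node hand computation", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(letters[1:3], letters[1:3])
  tom <- topological_overlap(a)
  ## (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  expect_equal(tom["a", "b"], 0.5, tolerance = 1e-12)
  expect_true(all(diag(tom) == 1))
  expect_true(isSymmetric(tom))

  ## block-diagonal adjacency keeps zero overlap across blocks
  b <- matrix(0, 4, 4)
  b[1:2, 1:2] <- 0.8; b[3:4, 3:4] <- 0.8; diag(b) <- 1
  tb <- topological_overlap(b)
  expect_equal(tb[1, 3], 0)
  expect_true(all(tb >= 0 & tb <= 1))
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
})

test_that("planted modules are recovered with high adjusted Rand index", {
  ## strong co-regulation regime: the module factor dominates noise
  aris <- vapply(1:5, function(s) {
    sim <- simulate_cohort(small_config(seed = s, module_amplitude = 1.5))
    tr <- sim$truth$analytes
    ids <- tr$analyte_id[tr$module_id > 0]
    nm <- run_network_modules(signal_abundance(sim), ids,
                              config = af_config(min_module_size = 10))
    adjusted_rand(tr$module_id[match(nm$assignment$analyte_id,
                                     tr$analyte_id)],
                  nm$assignment$module)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("pure-noise data yields only the background module", {
  set.seed(30)
  m <- matrix(rnorm(28 * 60), 28, 60,
              dimnames = list(sprintf("s%d", 1:28), sprintf("a%d", 1:60)))
  rho <- bicor_matrix(m)
  tom <- topological_overlap(signed_adjacency(rho, 22))
  suppressWarnings(asn <- detect_modules(tom, m, min_module_size = 20))
  expect_true(all(asn$module == 0))
  expect_equal(attr(asn, "n_modules"), 0L)
})

test_that("near-duplicate modules merge by eigenprofile correlation", {
  set.seed(31)
  n <- 28
  f <- rnorm(n)
  f2 <- f + rnorm(n, 0, 0.15)  # eigenprofiles correlate ~0.97
  g <- rnorm(n)
  m <- cbind(sapply(1:25, function(i) f + rnorm(n, 0, 0.3)),
             sapply(1:25, function(i) f2 + rnorm(n, 0, 0.3)),
             sapply(1:25, function(i) g + rnorm(n, 0, 0.3)))
  dimnames(m) <- list(sprintf("s%d", 1:n), sprintf("a%d", 1:75))
  rho <- bicor_matrix(m)
  tom <- topological_overlap(signed_adjacency(rho, 22))
  merged <- detect_modules(tom, m, min_module_size = 20, merge_corr = 0.85)
  expect_equal(attr(merged, "n_modules"), 2L)
  ## the two f-driven blocks share one label
  lab <- merged$module
  expect_equal(length(unique(lab[1:50])), 1L)
})

test_that("eigenprofiles summarize their members and rank hubs first", {
  ## module of identical profiles: variance explained 1, all kME 1
  set.seed(32)
  prof <- rnorm(20)
  m <- matrix(rep(prof, 5), 20, 5,
              dimnames = list(sprintf("s%d", 1:20), sprintf("a%d", 1:5)))
  m <- m + matrix(rnorm(100, 0, 1e-9), 20, 5)
  asn <- structure(data.frame(analyte_id = colnames(m), module = 1L),
                   class = c("af_modules", "data.frame"))
  eig <- module_eigenprofiles(m, asn)
  expect_equal(unname(eig$var_explained["M1"]), 1, tolerance = 1e-6)
  expect_true(all(eig$kme[, "M1"] > 0.999))
  ## unit-norm, positively oriented eigenprofile
  expect_equal(sum(eig$eigenprofiles[, 1]^2), 1, tolerance = 1e-8)
  expect_gt(mean(cor(m, eig$eigenprofiles[, 1])), 0)

  ## hubs: the analyte duplicating the eigenprofile ranks first
  m2 <- cbind(m, noisy = prof + rnorm(20, 0, 2))
  asn2 <- structure(data.frame(analyte_id = colnames(m2), module = 1L),
                    class = c("af_modules", "data.frame"))
  eig2 <- module_eigenprofiles(m2, asn2)
  hubs <- select_hubs(eig2$kme, asn2, n = 4)
  expect_false("noisy" %in% hubs$analyte_id)
  expect_equal(nrow(hubs), 4)
  ## n = module size returns the whole module
  all6 <- select_hubs(eig2$kme, asn2, n = 6)
  expect_setequal(all6$analyte_id, colnames(m2))
})

test_that("hubs carry larger true loadings than other members", {
  sim <- simulate_cohort(small_config(seed = 16, module_amplitude = 1.5))
  tr <- sim$truth$analytes
  ids <- tr$analyte_id[tr$module_id > 0]
  nm <- run_network_modules(signal_abundance(sim), ids,
                            config = af_config(min_module_size = 10))
  hub_load <- abs(tr$module_loading[match(nm$hubs$analyte_id,
                                          tr$analyte_id)])
  rest <- setdiff(ids, nm$hubs$analyte_id)
  rest_load <- abs(tr$module_loading[match(rest, tr$analyte_id)])
  expect_gt(mean(hub_load), mean(rest_load))
})

test_that("LOESS profiles reproduce known curves", {
  ga <- seq(16, 41, length.out = 28)
  lin <- 2 + 0.3 * ga
  fit <- loess_profile(ga, lin, span = 0.75)
  expect_lt(max(abs(fit$fitted - (2 + 0.3 * fit$ga))), 1e-6)

  const <- loess_profile(ga, rep(3, 28), span = 0.75)
  expect_lt(max(abs(const$fitted - 3)), 1e-8)

  quad <- 1 + 0.05 * (ga - 28)^2
  fq <- loess_profile(ga, quad, span = 0.75)
  truthq <- 1 + 0.05 * (fq$ga - 28)^2
  expect_lt(max(abs(fq$fitted - truthq)), 0.01 * diff(range(quad)))

  expect_error(loess_profile(ga[1:4], lin[1:4]), "at least 5")
  expect_error(loess_profile(ga, lin, span = 0), "span")
})
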