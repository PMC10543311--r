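test_that("cumulative counts step at the ion radius and respect wrapping", {
  ctr <- c(3.5, 3.5, 3.5)
  fr <- list(solute = matrix(ctr, 1),
             CL = matrix(ctr + c(1.00, 0, 0), 1),
             OW = matrix(ctr + c(2, 0, 0), 1))
  x <- manual_frames(list(fr))
  n <- cumulativeCounts(x, "CL")
  r <- attr(n, "r_nm")
  expect_true(all(n[r < 1.0 - 1e-9] == 0))
  expect_true(all(n[r >= 1.0] == 1))
  # wrapping: an ion just outside the box face is 0.1 + 3.5 - 3.5 away
  fr2 <- fr
  fr2$CL <- matrix(c(-0.1, 3.5, 3.5), 1)       # == box - 0.1 by periodicity
  fr3 <- fr
  fr3$CL <- matrix(c(7 - 0.1, 3.5, 3.5), 1)
  n2 <- cumulativeCounts(manual_frames(list(fr2)), "CL")
  n3 <- cumulativeCounts(manual_frames(list(fr3)), "CL")
  expect_equal(as.vector(n2), as.vector(n3))
  expect_error(cumulativeCounts(x, "CL", r_max_nm = 4), "minimum-image")
})

test_that("uniform ions accumulate as r^3", {
  set.seed(5)
  bx <- simulateSolvationBox(n_frames = 10, n_water = 200, salt_M = 5,
                             seed = 5)  # dense ions for counting statistics
  n <- colMeans(cumulativeCounts(bx, "CL"))
  r <- attr(cumulativeCounts(bx, "CL"), "r_nm")
  i1 <- which.min(abs(r - 1.5)); i2 <- which.min(abs(r - 3.0))
  expect_equal(n[i2] / n[i1], 8, tolerance = 0.15)
})

test_that("bulk ratio matches constructed and analytic values", {
  set.seed(6)
  ctr <- c(3.5, 3.5, 3.5)
  shell_pt <- function(n, lo = 2.5, hi = 3.38) {
    # uniform directions at uniform-in-volume radii inside the shell
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- (stats::runif(n, lo^3, hi^3))^(1 / 3)
    sweep(u * rad, 2, ctr, `+`)
  }
  fr <- list(solute = matrix(ctr, 1), CL = shell_pt(10), OW = shell_pt(1000))
  x <- manual_frames(list(fr))
  expect_equal(bulkRatio(x, "CL"), 0.01)
  # uniform box: shell ratio approaches the overall mole ratio
  bx <- simulateSolvationBox(n_frames = 20, n_water = 3000, seed = 7)
  expect_equal(bulkRatio(bx, "CL"),
               bx@meta$n_anion / (3000 * 343 / 7^3) * (7^3 / 343),
               tolerance = 0.1)
  # rigid translation (with wrapping) leaves the ratio unchanged
  shift <- function(m) (m + 1.7) %% 7
  fr_t <- lapply(fr, shift)
  expect_equal(bulkRatio(manual_frames(list(fr_t)), "CL"),
               bulkRatio(x, "CL"))
})

test_that("gamma matches the brute-force local-bulk definition", {
  set.seed(8)
  bx <- simulateSolvationBox(n_frames = 10, n_water = 800, seed = 8)
  g <- gammaIon(bx, "CL")
  shell <- c(2.5, 3.38)
  # independent brute-force oracle: plain distance loops, no histograms
  brute <- sapply(c(1.0, 2.0, 3.0), function(r_eval) {
    per_frame <- sapply(bx@frames, function(fr) {
      ref <- colMeans(fr$solute)
      dist_to <- function(m) {
        d <- sweep(m, 2, ref)
        d <- d - 7 * round(d / 7)
        sqrt(rowSums(d^2))
      }
      di <- dist_to(fr$CL); dw <- dist_to(fr$OW)
      ratio <- sum(di > shell[1] & di <= shell[2]) /
        sum(dw > shell[1] & dw <= shell[2])
      sum(di <= r_eval) - sum(dw <= r_eval) * ratio
    })
    mean(per_frame)
  })
  at <- vapply(c(1.0, 2.0, 3.0), function(rr)
    g$gamma[which.min(abs(g$r_nm - rr))], numeric(1))
  expect_equal(at, brute, tolerance = 1e-9)
})

test_that("uniform box shows no preferential interaction (null case)", {
  bx <- simulateSolvationBox(n_frames = 20, seed = 9)
  g <- gammaIon(bx, "CL")
  pooled <- colSums(cumulativeCounts(bx, "CL"))
  sel <- pooled >= 10   # radii with valid counting statistics
  expect_true(all(abs(g$gamma[sel]) < 3 * g$sem[sel]))
  # bulk-shell self-consistency: gamma ~ 0 where the normalization lives
  i <- which.min(abs(g$r_nm - 3.0))
  expect_lt(abs(g$gamma[i]), 3 * g$sem[i])
})

test_that("an anion-excluded sphere matches the closed-form excess", {
  wa <- function(r) as.numeric(r >= 1)
  bx <- simulateSolvationBox(n_frames = 20, w_anion = wa, seed = 10)
  g <- gammaIon(bx, "CL")
  v_exc <- 4 / 3 * pi * 1^3
  pred <- -bx@meta$n_anion / (7^3 - v_exc) * v_exc
  sel <- g$r_nm > 1.2 & g$r_nm < 3.4
  expect_true(all(abs(g$gamma[sel] - pred) < 3 * g$sem[sel]))
  # sign check against the uniform cation of the same box
  gc <- gammaIon(bx, "K")
  i3 <- which.min(abs(g$r_nm - 3))
  expect_lt(g$gamma[i3], gc$gamma[i3])
})

test_that("replicate lists give SEM across replicates, scaling as 1/sqrt(n)", {
  reps16 <- lapply(1:16, function(i)
    simulateSolvationBox(n_frames = 5, n_water = 1000, seed = 100 + i,
                         replicate = i))
  g4 <- gammaIon(reps16[1:4], "CL")
  g16 <- gammaIon(reps16, "CL")
  expect_false(attr(g4, "flagged"))
  sel <- g4$r_nm > 1 & g4$r_nm < 3
  ratio <- mean(g4$sem[sel]) / mean(g16$sem[sel])
  expect_gt(ratio, 1.3)   # expected 2 with 4 -> 16 replicates
  expect_lt(ratio, 3)
  # a single frame gives no SEM and is flagged
  one <- simulateSolvationBox(n_frames = 1, n_water = 500, seed = 3)
  g1 <- gammaIon(one, "CL")
  expect_true(attr(g1, "flagged"))
  expect_true(all(is.na(g1$sem)))
})

test_that("whole-salt combination is exact pointwise arithmetic", {
  r <- seq(0.02, 3, by = 0.02)
  ga <- data.frame(r_nm = r, gamma = rep(1, length(r)), sem = 0.1)
  gc <- data.frame(r_nm = r, gamma = rep(3, length(r)), sem = 0.2)
  gs <- gammaSalt(ga, gc, Z = -2)
  expect_true(all(gs$gamma == 0.5 * (1 + 3 - 2)))
  expect_equal(gs$sem, rep(0.5 * sqrt(0.1^2 + 0.2^2), length(r)))
  g0 <- gammaSalt(data.frame(r_nm = r, gamma = 0, sem = 0),
                  data.frame(r_nm = r, gamma = 0, sem = 0), Z = 0)
  expect_true(all(g0$gamma == 0))
  # brute-force pointwise identity on arbitrary profiles
  set.seed(11)
  ga$gamma <- stats::rnorm(length(r)); gc$gamma <- stats::rnorm(length(r))
  gs2 <- gammaSalt(ga, gc, Z = 1)
  expect_equal(gs2$gamma, 0.5 * (ga$gamma + gc$gamma - 1))
  expect_error(gammaSalt(ga, gc[-1, ], Z = 0), "grid")
})

test_that("profile differences are antisymmetric and sign-correct", {
  wa <- function(r) ifelse(r < 1.2, 0.2, 1)   # glutamate-like exclusion
  glu <- gammaIon(simulateSolvationBox(n_frames = 15, w_anion = wa,
                                       seed = 12), "CL")
  cl <- gammaIon(simulateSolvationBox(n_frames = 15, seed = 13), "CL")
  d <- deltaGamma(glu, cl, r_eval_nm = 3.0)
  expect_lt(d$delta, 0)   # excluded anion sits below the uniform one
  d_rev <- deltaGamma(cl, glu, r_eval_nm = 3.0)
  expect_equal(d$delta, -d_rev$delta)
  expect_equal(deltaGamma(cl, cl)$delta, 0)
  expect_error(deltaGamma(glu, cl, r_eval_nm = 5), "outside")
})

test_that("site-site RDF is flat for ideal gas and zero under exclusion", {
  set.seed(14)
  mk_frame <- function() list(
    solute = matrix(c(3.5, 3.5, 3.5), 1),
    A = matrix(stats::runif(600, 0, 7), ncol = 3),
    B = matrix(stats::runif(600, 0, 7), ncol = 3))
  x <- manual_frames(lapply(1:20, function(i) mk_frame()))
  rdf <- siteRdf(x, "A", "B")
  sel <- rdf$r_nm > 0.5 & rdf$r_nm < 3.4
  expect_lt(mean(abs(rdf$g[sel] - 1)), 0.05)
  expect_equal(mean(rdf$g[sel]), 1, tolerance = 0.02)
  # hard exclusion below 0.3 nm
  mk_excl <- function() {
    f <- mk_frame()
    ctr <- c(3.5, 3.5, 3.5)
    d <- sqrt(rowSums(sweep(f$B, 2, ctr)^2))
    f$A <- matrix(ctr, 1)
    f$B <- f$B[d >= 0.3, , drop = FALSE]
    f
  }
  fr <- mk_excl()
  x2 <- SolvationFrames(list(fr), box = 7)
  rdf2 <- siteRdf(x2, "A", "B")
  expect_true(all(rdf2$g[rdf2$r_nm < 0.29] == 0))
  expect_error(siteRdf(x, "missing", "B"), "selector")
})

test_that("RDF integral reproduces the cumulative counts", {
  set.seed(15)
  bx <- simulateSolvationBox(n_frames = 5, n_water = 500, seed = 15,
                             solute_xyz = matrix(c(3.5, 3.5, 3.5), 1))
  rdf <- siteRdf(bx, "solute", "CL", bin_nm = 0.02)
  n <- colMeans(cumulativeCounts(bx, "CL", bin_nm = 0.02))
  rho <- bx@meta$n_anion / 7^3
  integral <- cumsum(rho * rdf$g * 4 * pi * rdf$r_nm^2 * 0.02)
  i <- which.min(abs(rdf$r_nm - 3))
  expect_equal(integral[i], n[i], tolerance = 0.02)
})

test_that("profiles are invariant under rigid rotation and translation", {
  bx <- simulateSolvationBox(n_frames = 5, n_water = 400, seed = 16)
  rot <- function(m) {  # 90-degree rotation about z through the box centre
    d <- sweep(m, 2, c(3.5, 3.5, 0))
    cbind(-d[, 2], d[, 1], d[, 3]) + rep(c(3.5, 3.5, 0), each = nrow(m))
  }
  fr_rot <- lapply(bx@frames, function(f) lapply(f, rot))
  bx_rot <- SolvationFrames(fr_rot, box = 7)
  expect_equal(gammaIon(bx_rot, "CL")$gamma, gammaIon(bx, "CL")$gamma)
  shift <- function(m) sweep(m, 2, c(1.1, 0.4, 2.2), `+`) %% 7
  fr_sh <- lapply(bx@frames, function(f) lapply(f, shift))
  bx_sh <- SolvationFrames(fr_sh, box = 7)
  expect_equal(gammaIon(bx_sh, "CL")$gamma, gammaIon(bx, "CL")$gamma)
})
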