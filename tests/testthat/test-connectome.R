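test_that("structural connectome weights are tract volume relative to ICV", {
  tv <- data.frame(region_i = c(1, 2, 5), region_j = c(2, 3, 6),
                   n_tracts = c(3, 1, 2),
                   total_tract_voxels = c(100, 50, 10))
  sc <- build_sc(tv, voxel_volume = 8, icv = 1.5e6)
  expect_equal(sc$weights[1, 2], 100 * 8 / 1.5e6)  # 5.333e-4
  expect_equal(sc$weights[2, 1], sc$weights[1, 2])
  expect_equal(sc$weights[2, 3], 0)                # single tract: spurious
  expect_equal(sc$weights[5, 6], 10 * 8 / 1.5e6)
  expect_true(all(diag(sc$weights) == 0))

  empty <- build_sc(tv[0, ], voxel_volume = 8, icv = 1.5e6)
  expect_true(all(empty$weights == 0))

  expect_error(build_sc(transform(tv, n_tracts = c(-1, 1, 2)), 8, 1.5e6),
               "negative")
  bad <- data.frame(region_i = 4, region_j = 4, n_tracts = 3,
                    total_tract_voxels = 10)
  expect_error(build_sc(bad, 8, 1.5e6), "self-connections")
})

test_that("functional connectome is the nuisance-adjusted clipped correlation", {
  set.seed(1)
  tlen <- 60
  nuis <- matrix(rnorm(tlen * 8), tlen)
  y <- rnorm(tlen)
  ts <- cbind(y, y, -y + 1e-8 * rnorm(tlen), rnorm(tlen))
  fc <- build_fc(ts, nuis * 0)
  expect_equal(fc$weights[1, 2], 1)              # identical series
  expect_equal(fc$weights[1, 3], 0)              # anti-correlated: clipped
  expect_true(all(fc$weights >= 0 & fc$weights <= 1))
  expect_true(all(diag(fc$weights) == 0))
})

test_that("nuisance regression matches the explicit projection oracle", {
  set.seed(2)
  tlen <- 80
  nuis <- matrix(rnorm(tlen * 8), tlen)
  base <- rnorm(tlen)
  # series 2 = series 1 + nuisance effect: residual correlation must be 1
  ts <- cbind(base, base + nuis %*% rnorm(8), matrix(rnorm(tlen * 3), tlen))
  fc <- build_fc(ts, nuis)
  expect_equal(fc$weights[1, 2], 1, tolerance = 1e-10)
  for (pair in list(c(1, 3), c(2, 4), c(3, 5))) {
    ref <- oracle_partial_cor(ts[, pair[1]], ts[, pair[2]], nuis)
    expect_equal(fc$weights[pair[1], pair[2]], max(0, min(1, ref)),
                 tolerance = 1e-10)
  }
})

test_that("overall connectivity is the mean over all region pairs", {
  w <- matrix(0, 94, 94)
  expect_equal(overall_connectivity(connectome(w)), 0)
  w[3, 10] <- w[10, 3] <- 0.7
  expect_equal(overall_connectivity(connectome(w)), 0.7 / 4371)
  # permutation invariance under simultaneous relabeling
  set.seed(4)
  w <- random_weights(20)
  perm <- sample(20)
  expect_equal(overall_connectivity(w[perm, perm]), overall_connectivity(w))
})

test_that("group averaging uses prevalence for SC and mean weight for FC", {
  mk <- function(vals, modality) {
    w <- matrix(0, 4, 4)
    w[1, 2] <- w[2, 1] <- vals[1]
    w[3, 4] <- w[4, 3] <- vals[2]
    connectome(w, modality)
  }
  scs <- list(mk(c(1, 2), "SC"), mk(c(3, 0), "SC"), mk(c(0.5, 0), "SC"),
              mk(c(2, 0), "SC"))
  g <- group_average(scs)
  expect_equal(g$weights[1, 2], 1)     # present in 4 of 4
  expect_equal(g$weights[3, 4], 0.25)  # present in 1 of 4
  fcs <- list(mk(c(0.2, 0.6), "FC"), mk(c(0.4, 0), "FC"))
  gf <- group_average(fcs)
  expect_equal(gf$weights[1, 2], 0.3)
  expect_equal(gf$weights[3, 4], 0.3)
  expect_error(group_average(list(mk(c(1, 1), "SC"), connectome(matrix(0, 5, 5)))),
               "mismatch")
})

test_that("proportional thresholding keeps 874 of 4371 pairs at sparsity 0.80", {
  set.seed(5)
  g <- connectome(random_weights(94, density = 0.9, seed = 5), "SC")
  m <- proportional_threshold(g, 0.80)
  expect_equal(m$n_edges, 874)
  expect_equal(sum(m$edges[upper.tri(m$edges)]), 874)
  # ties: an all-equal matrix still yields exactly K edges, chosen by the
  # documented (row, column) order, deterministically
  ones <- matrix(1, 94, 94); diag(ones) <- 0
  m1 <- proportional_threshold(connectome(ones), 0.80)
  m2 <- proportional_threshold(connectome(ones), 0.80)
  expect_equal(m1$n_edges, 874)
  expect_identical(m1$edges, m2$edges)
  ut <- which(upper.tri(ones), arr.ind = TRUE)
  first <- ut[order(ut[, 1], ut[, 2]), ][1:874, ]
  expect_true(all(m1$edges[first]))
})

test_that("thresholding agrees with a brute-force sort on a small toy", {
  set.seed(6)
  w <- matrix(0, 5, 5)
  vals <- sample(10)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  m <- proportional_threshold(connectome(w), 0.9)  # K = round(0.1*10) = 1
  expect_equal(m$n_edges, 1)
  top <- which(w == max(vals), arr.ind = TRUE)
  expect_true(m$edges[top[1, 1], top[1, 2]])
  expect_error(proportional_threshold(connectome(w), 0.99), "no edges")
})

test_that("masks are nested across sparsities (monotone thresholding)", {
  set.seed(7)
  for (i in 1:5) {
    w <- random_weights(30, density = 0.6, seed = i)
    w[w > 0] <- round(w[w > 0], 1)  # induce ties
    masks <- lapply(c(0.5, 0.7, 0.9), function(s)
      proportional_threshold(connectome(w), s)$edges)
    expect_true(all(masks[[2]] <= masks[[1]]))
    expect_true(all(masks[[3]] <= masks[[2]]))
  }
})

test_that("prevalence mode implements the literal group-presence cut", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.2
  w[3, 4] <- w[4, 3] <- 0.25
  m <- proportional_threshold(connectome(w), 0.75, mode = "prevalence")
  expect_true(m$edges[1, 2])    # prevalence 0.9 >= 0.25
  expect_true(m$edges[3, 4])
  expect_false(m$edges[1, 3])   # 0.2 < 0.25
})

test_that("group masking zeroes outside edges and never densifies", {
  set.seed(8)
  w <- random_weights(20, density = 0.5, seed = 8)
  c0 <- connectome(w)
  full <- proportional_threshold(connectome(matrix(1, 20, 20) - diag(20)), 1e-6)
  expect_equal(apply_group_mask(c0, full)$weights, c0$weights,
               ignore_attr = TRUE)
  zero <- connectome(matrix(0, 20, 20))
  m <- proportional_threshold(connectome(random_weights(20, seed = 9)), 0.8)
  expect_true(all(apply_group_mask(zero, m)$weights == 0))
  for (i in 1:5) {
    ci <- connectome(random_weights(20, density = 0.4, seed = 10 + i))
    masked <- apply_group_mask(ci, m)
    sp_ind <- 1 - sum(masked$weights[upper.tri(masked$weights)] > 0) / 190
    expect_gte(sp_ind, m$sparsity - 1e-12)
  }
})

test_that("interhemispheric fraction counts cross-hemisphere retained edges", {
  edges <- matrix(FALSE, 6, 6)
  hemi <- c("L", "R", "L", "R", "L", "R")
  edges[1, 3] <- edges[3, 1] <- TRUE    # L-L
  m <- structure(list(edges = edges, sparsity = NA, n_edges = 1),
                 class = "edge_mask")
  expect_equal(interhemispheric_fraction(m, hemi), 0)
  edges[1, 2] <- edges[2, 1] <- TRUE    # L-R
  m$edges <- edges
  expect_equal(interhemispheric_fraction(m, hemi), 0.5)
  # alternating-hemisphere complete toy: enumerate directly
  w <- matrix(runif(64), 8, 8); w <- (w + t(w)) / 2; diag(w) <- 0
  mask <- proportional_threshold(connectome(w), 0.5)
  ut <- which(upper.tri(mask$edges) & mask$edges, arr.ind = TRUE)
  hemi8 <- ifelse(1:8 %% 2 == 1, "L", "R")
  expect_equal(interhemispheric_fraction(mask, hemi8),
               mean(hemi8[ut[, 1]] != hemi8[ut[, 2]]))
})

test_that("connectomes and edge lists round-trip through disk", {
  set.seed(9)
  c0 <- connectome(random_weights(10, seed = 9), "SC")
  path <- tempfile(fileext = ".csv")
  write_connectome(c0, path)
  back <- read_connectome(path, "SC")
  expect_equal(back$weights, c0$weights, ignore_attr = TRUE)
  ep <- tempfile(fileext = ".tsv")
  write_edge_list(c0, ep)
  el <- read.delim(ep)
  expect_equal(nrow(el), sum(c0$weights[upper.tri(c0$weights)] > 0))
  expect_equal(c0$weights[cbind(el$i, el$j)], el$weight)
})
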