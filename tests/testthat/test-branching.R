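test_that("MBI follows the counting rule in exact integer arithmetic", {
  # unbranched organelle: floor of the formula
  r0 <- mbi_from_counts(branch_counts(0, 0, 0, 0))
  expect_identical(r0$tbi, 1L)
  expect_identical(r0$lbi, 1L)
  expect_equal(r0$mbi, 1)
  expect_equal(r0$mbi_class, "equal")

  # 3 myofibrils bridged; 1 half sarcomere + 1 z-band longitudinally
  r1 <- mbi_from_counts(branch_counts(3, 0, 1, 1))
  expect_identical(r1$tbi, 4L)
  expect_identical(r1$lbi, 3L)
  expect_equal(r1$mbi, 4 / 3)
  expect_equal(r1$mbi_class, "transverse")

  # one full sarcomere counts double in the longitudinal indicator
  r2 <- mbi_from_counts(branch_counts(0, 1, 0, 0))
  expect_identical(r2$tbi, 1L)
  expect_identical(r2$lbi, 3L)
  expect_equal(r2$mbi, 1 / 3)
  expect_equal(r2$mbi_class, "longitudinal")

  expect_error(branch_counts(-1, 0, 0, 0), "non-negative")
  expect_error(branch_counts(0.5, 0, 0, 0), "non-negative")
})

test_that("classification at MBI = 1 has no floating-point ambiguity", {
  # tbi == lbi must classify equal however the ratio rounds
  r <- mbi_from_counts(branch_counts(2, 1, 0, 0))  # 3/3
  expect_equal(r$mbi_class, "equal")
  r <- mbi_from_counts(branch_counts(6, 2, 1, 1))  # 7/7
  expect_equal(r$mbi_class, "equal")
})

test_that("geometric counts recover constructed skeleton extents", {
  w <- 1000; s <- 2000
  rod <- function(p1, p2, n = 20) {
    t <- seq(0, 1, length.out = n)
    nodes <- cbind(p1[1] + t * (p2[1] - p1[1]),
                   p1[2] + t * (p2[2] - p1[2]),
                   p1[3] + t * (p2[3] - p1[3]))
    skeleton_graph(nodes, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
  }
  # straight transverse rod spanning exactly 3 myofibril widths
  sk_t <- rod(c(0, 0, 0), c(3 * w, 0, 0))
  ct <- branch_counts_geometric(sk_t, myofibril_width = w,
                                sarcomere_length = s)
  expect_identical(ct$myofibrils_bridged, 3L)
  expect_identical(ct$sarcomeres, 0L)
  expect_true(attr(ct, "approximate"))

  # straight longitudinal rod spanning one sarcomere between z-bands
  sk_l <- rod(c(0, 0, 0), c(0, 0, s))
  cl <- branch_counts_geometric(sk_l, myofibril_width = w,
                                sarcomere_length = s,
                                zband_positions = c(0, s, 2 * s))
  expect_identical(cl$sarcomeres, 1L)
  expect_identical(cl$myofibrils_bridged, 0L)
  # the sarcomere's own bounding planes are not double counted
  expect_identical(cl$z_bands, 0L)
  expect_false(attr(cl, "approximate"))

  # the home plane itself never counts as a crossing
  sk_z <- rod(c(0, 0, -300), c(0, 0, 300))
  cz <- branch_counts_geometric(sk_z, myofibril_width = w,
                                sarcomere_length = s,
                                zband_positions = c(0, s))
  expect_identical(cz$z_bands, 0L)
  # a short projection through a neighboring plane (closer than a half
  # sarcomere, as with locally irregular z-band spacing) counts one
  sk_z3 <- rod(c(0, 0, -100), c(0, 0, 700))
  cz3 <- branch_counts_geometric(sk_z3, myofibril_width = w,
                                 sarcomere_length = s,
                                 zband_positions = c(0, 600))
  expect_identical(cz3$z_bands, 1L)
  expect_identical(cz3$sarcomeres, 0L)

  # point skeleton: all counts zero
  pt <- skeleton_graph(matrix(c(0, 0, 0), 1), matrix(integer(), 0, 2))
  cp <- branch_counts_geometric(pt)
  expect_equal(unlist(cp[1:4]), c(myofibrils_bridged = 0L,
                                  sarcomeres = 0L,
                                  half_sarcomeres = 0L, z_bands = 0L))
})

test_that("sarcomere spanning is inclusive at the boundary", {
  rod_z <- function(len) {
    n <- 5
    t <- seq(0, len, length.out = n)
    skeleton_graph(cbind(0, 0, t), cbind(1:(n - 1), 2:n))
  }
  expect_false(spans_sarcomere(rod_z(1900), sarcomere_length = 2000))
  expect_true(spans_sarcomere(rod_z(2000), sarcomere_length = 2000))
  pt <- skeleton_graph(matrix(c(0, 0, 0), 1), matrix(integer(), 0, 2))
  expect_false(spans_sarcomere(pt, sarcomere_length = 2000))
})

test_that("population MBI proportions sum to 1 and recover the mix", {
  expect_equal(classify_mbi_population(rep("equal", 5)),
               c(transverse = 0, equal = 1, longitudinal = 0),
               ignore_attr = TRUE)
  expect_error(classify_mbi_population(character()), "no MBI")

  # generator truth: realized class mix within binomial error
  vol <- generate_fiber_volume(n_mitochondria = 48, seed = 5,
                               nanotunnel_rate = 0,
                               voxel_size = c(40, 40, 80))
  tr <- attr(vol, "truth")$organelles
  res <- lapply(seq_len(nrow(tr)), function(i)
    mbi_from_counts(branch_counts(tr$myofibrils_bridged[i],
                                  tr$sarcomeres[i],
                                  tr$half_sarcomeres[i], tr$z_bands[i])))
  prop <- classify_mbi_population(res)
  expect_equal(sum(prop), 1)
  mix <- c(0.404, 0.506, 0.091) / sum(c(0.404, 0.506, 0.091))
  se <- sqrt(mix * (1 - mix) / 48)
  expect_true(all(abs(prop - mix) < 3.5 * se + 1e-9))
})

test_that("skeletons validate connectivity and positive arc lengths", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5))
  expect_error(skeleton_graph(nodes, rbind(c(1, 2))), "connected")
  expect_error(skeleton_graph(rbind(c(0, 0, 0), c(0, 0, 0)),
                              rbind(c(1, 2))), "zero-length")
  expect_error(skeleton_graph(nodes, rbind(c(1, 4))), "out of range")
})
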