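make_flat_pair <- function(z_lo = -2, z_hi = 2, nx = 8, ny = 8, spacing = 2) {
  grid_xy <- expand.grid(x = (seq_len(nx) - (nx + 1) / 2) * spacing,
                         y = (seq_len(ny) - (ny + 1) / 2) * spacing)
  lo <- toy_structure(cbind(grid_xy$x, grid_xy$y, z_lo), chain = "A",
                      label = "lower")
  hi <- toy_structure(cbind(grid_xy$x, grid_xy$y, z_hi), chain = "B",
                      label = "upper")
  list(a = lo, b = hi)
}

test_that("orientation puts the centroid axis on Z with the midpoint at origin", {
  p <- make_flat_pair()
  ## centroids on the X axis before orientation
  a <- transform_structure(p$a, diag(3)[c(3, 2, 1), ])   # swap x/z
  b <- transform_structure(p$b, diag(3)[c(3, 2, 1), ])
  o <- orient_complex(a, b)
  d_ab <- unname(centroid(o$b) - centroid(o$a))
  expect_equal(d_ab[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(d_ab[3], 4, tolerance = 1e-9)             # distance preserved
  expect_equal(unname(centroid(o$a) + centroid(o$b)), rep(0, 3),
               tolerance = 1e-9)
  expect_error(orient_complex(p$a, p$a), "coincide")
})

test_that("orientation is invariant to rigid pre-motions of the complex", {
  set.seed(99)
  sp <- synth_spec(12, nx = 6, ny = 6)
  dm <- make_dimer(sp)
  ref <- orient_complex(dm$a, dm$b)
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, 0, 20)
    o <- orient_complex(transform_structure(dm$a, R, t),
                        transform_structure(dm$b, R, t))
    expect_equal(coords(o$a), coords(ref$a), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(coords(o$b), coords(ref$b), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("flat parallel slabs give a planar midpoint surface", {
  p <- make_flat_pair(-2, 2)
  s <- build_surface(p$a, p$b, step = 1, gap_threshold = 8)
  expect_true(all(abs(s$nodes$z[s$nodes$defined]) < 1e-9))
  ## midpoint property: z - lower == upper - z
  nd <- s$nodes[s$nodes$defined, ]
  expect_equal(nd$z - nd$lower, nd$upper - nd$z, tolerance = 1e-9)
  ## gap 4 above a threshold of 3: no nodes, hard error
  expect_error(build_surface(p$a, p$b, gap_threshold = 3), "not in contact")
})

test_that("a tilted upper slab produces a linearly varying midpoint", {
  grid_xy <- expand.grid(x = seq(-6, 6, 1), y = seq(-6, 6, 1))
  lo <- toy_structure(cbind(grid_xy$x, grid_xy$y, -3), label = "lower")
  hi <- toy_structure(cbind(grid_xy$x, grid_xy$y, 3 + 0.2 * grid_xy$x),
                      label = "upper")
  s <- build_surface(lo, hi, step = 1, gap_threshold = 20)
  nd <- s$nodes[s$nodes$defined & abs(s$nodes$x) <= 5 & abs(s$nodes$y) <= 5, ]
  ## analytic midpoint of the planes z = -3 and z = 3 + 0.2 x, allowing for
  ## the capture-radius discretisation of the upper bound
  expect_true(all(abs(nd$z - (0.1 * nd$x)) <= 0.1))
})

test_that("cylinder weights follow membership fraction and Gauss decay", {
  ## residue 1 fully inside at the node, residue 2 straddles the boundary
  xyz <- rbind(c(0, 0, 1), c(0.5, 0, 1),         # residue 1, inside r = 4
               c(3.9, 0, 1), c(4.2, 0, 1))       # residue 2: 2 of its atoms? no: 1 in, 1 out
  s <- toy_structure(xyz, res_of = c(1, 1, 2, 2))
  nb <- cylinder_neighborhood(s, c(0, 0, 0), r = 4, h = 10)
  expect_equal(nrow(nb), 2)
  r1 <- nb[nb$res_key == "A:1", ]; r2 <- nb[nb$res_key == "A:2", ]
  expect_equal(r1$f, 1)
  expect_equal(r1$w, 1)                          # nearest residue: exponent 0
  expect_equal(r2$f, 0.5)
  ## w ratio between residues at mean distances d1 < d2 is f2 * exp(-(d2-d1)^2/h)
  expect_equal(r2$w, r2$f * exp(-(r2$d - r1$d)^2 / 10))
  ## weight never exceeds membership and is maximal for the closest residue
  expect_true(all(nb$w <= nb$f + 1e-12))
  ## empty cylinder: zero-row neighbourhood
  expect_equal(nrow(cylinder_neighborhood(s, c(100, 100, 0), r = 4)), 0)
})

test_that("diversity maps localise a planted polymorphic patch", {
  sp <- synth_spec(21, nx = 8, ny = 8, jitter = 0.05)
  patch <- slab_patch_columns(sp, c(0, 0), 3)
  aln <- make_population(sp, patch_cols = patch)
  dm <- make_dimer(sp, aln, aln)
  o <- orient_complex(dm$a, dm$b)
  s <- build_surface(o$a, o$b)
  mp <- map_structure_to_alignment(o$a, aln)
  map <- diversity_map(s, o$a, aln, mp, "pi")
  nd <- s$nodes
  ok <- which(map$status == "ok")
  vals <- map$value[ok]
  r_node <- sqrt(nd$x[ok]^2 + nd$y[ok]^2)
  ## signal concentrates near the patch: every node > 9 A away is quieter
  ## than the peak near the centre
  expect_gt(max(vals[r_node < 3]), 0)
  expect_true(all(vals[r_node > 9] < max(vals[r_node < 3])))
  ## far background is monomorphic
  expect_true(all(vals[r_node > 12] == 0))
})

test_that("monomorphic populations give an all-zero map", {
  sp <- synth_spec(22, nx = 6, ny = 6, n_hap_nt = 1, n_hap_aa = 1)
  aln <- make_population(sp)
  dm <- make_dimer(sp, aln, aln)
  o <- orient_complex(dm$a, dm$b)
  s <- build_surface(o$a, o$b)
  map <- diversity_map(s, o$a, aln, map_structure_to_alignment(o$a, aln), "pi")
  expect_true(all(map$value[map$status == "ok"] == 0))
})

test_that("in the wide-cylinder flat-bandwidth limit every node sees global pi", {
  sp <- synth_spec(23, nx = 5, ny = 5, jitter = 0)
  aln <- make_population(sp, patch_cols = 1:25)
  dm <- make_dimer(sp, aln, aln)
  o <- orient_complex(dm$a, dm$b)
  s <- build_surface(o$a, o$b)
  mp <- map_structure_to_alignment(o$a, aln)
  ## r covers the whole slab, h -> infinity: f = 1, w = 1 for all residues
  map <- diversity_map(s, o$a, aln, mp, "pi", r = 1000, h = 1e12)
  gl <- pi_sites(aln)
  ok <- map$status == "ok"
  expect_equal(map$value[ok], rep(gl, sum(ok)), tolerance = 1e-9)
})

test_that("dN/dS maps carry sentinels where variation is one-sided or absent", {
  sp <- synth_spec(24, nx = 5, ny = 5, n_hap_nt = 6, n_hap_aa = 1)
  aln <- make_population(sp, patch_cols = 1:25)   # synonymous-only population
  dm <- make_dimer(sp, aln, aln)
  o <- orient_complex(dm$a, dm$b)
  s <- build_surface(o$a, o$b)
  map <- diversity_map(s, o$a, aln, map_structure_to_alignment(o$a, aln),
                       "dnds", r = 1000, h = 1e12)
  ok <- map$status != "undefined"
  ## with purely synonymous variation the global ratio is 0 everywhere
  expect_true(all(map$status[ok] == "ok"))
  expect_true(all(map$value[ok] == 0))
})
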