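# Restriction-site scanning, circular fragment arithmetic, and
# triangulation of cleavage sites from fragment-length observations.

test_that("cut positions agree with an independent regex scan for every marker enzyme", {
  mc <- minicircle_sequence("336")
  specs <- builtin_enzymes()
  for (nm in c("EcoRV", "XmnI", "NdeI", "MseI", "BbvCI")) {
    e <- specs[[nm]]
    got <- find_cut_positions(mc, e)
    want <- oracle_find_cuts(mc$bases, e$recognition, e$cut_offset_top,
                             e$cut_offset_bottom)
    expect_identical(got, want)
    expect_length(got, 1L)  # each marker cuts the minicircle exactly once
  }
  # enzymes appear along the sequence in the order they are listed
  rmap <- std_map()
  expect_identical(rmap$entries$enzyme[order(rmap$entries$position)],
                   c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
  # EcoRV (GAT^ATC) cut falls at position 41
  expect_identical(find_cut_positions(mc, "EcoRV"), 41L)
})

test_that("motif matching wraps across the circular origin", {
  tiny <- circular_sequence("AATTAATT")
  mse <- builtin_enzymes()$MseI
  got <- find_cut_positions(tiny, mse)
  expect_identical(got, oracle_find_cuts(tiny$bases, "TTAA", 1, 3))
  expect_true(7L %in% got)  # site TTAA spans positions 7,8,1,2
  # absent motif
  expect_identical(find_cut_positions(tiny, enzyme_spec("EcoRV", "GATATC", 3)),
                   integer(0))
  # nicking enzymes scan the motif-bearing strand only
  nick <- find_cut_positions(minicircle_sequence("336"),
                             builtin_enzymes()$Nb.BbvCI)
  expect_length(nick, 1L)
  expect_error(enzyme_spec("bad", "GATAXC", 3), "X")
})

test_that("rotating the origin shifts cuts and estimates, preserves lengths", {
  mc <- minicircle_sequence("336")
  N <- mc$length
  for (r in c(1, 50, 143, 335)) {
    rot <- circular_sequence(rotate_bases(mc$bases, r), "rotated")
    for (nm in c("EcoRV", "MseI", "BbvCI")) {
      p0 <- find_cut_positions(mc, nm)
      p1 <- find_cut_positions(rot, nm)
      expect_identical(p1, sort(as.integer(rotate_position(p0, r, N))))
    }
    # triangulated site shifts with the origin; fragment data regenerated
    map0 <- std_map()
    map1 <- restriction_map(rot, c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
    x <- 143
    obs0 <- gen_fragment_observations(data.frame(position = x, weight = 1),
                                      map0, length_sd = 0, seed = 5)
    obs1 <- gen_fragment_observations(
      data.frame(position = rotate_position(x, r, N), weight = 1),
      map1, length_sd = 0, seed = 5)
    e0 <- triangulate_sites(obs0, map0)
    e1 <- triangulate_sites(obs1, map1)
    expect_equal(e1$position[1], rotate_position(e0$position[1], r, N))
    expect_equal(sort(fragment_lengths(map1$entries$position, N)),
                 sort(fragment_lengths(map0$entries$position, N)))
  }
})

test_that("fragment lengths are circular gaps that conserve the circle size", {
  expect_identical(fragment_lengths(c(41, 143), 336), c(102L, 234L))
  expect_identical(fragment_lengths(143, 336), 336L)
  expect_identical(fragment_lengths(c(10, 178), 336), c(168L, 168L))
  set.seed(3)
  for (i in 1:20) {
    N <- sample(100:1000, 1)
    cuts <- sample(N, sample(1:8, 1))
    expect_identical(sum(fragment_lengths(cuts, N)), as.integer(N))
  }
  expect_error(fragment_lengths(integer(0), 336), "cut")
  expect_error(fragment_lengths(400, 336), "1..N")
})

test_that("noiseless triangulation recovers arbitrary sites exactly", {
  # sites whose mirror about every reference cut (at circular distance
  # 2d mod N, so both cuts and their antipodes matter) stays outside
  # the cluster threshold, so no mirror merges with the true cluster
  rmap <- std_map()
  for (x in c(1, 100, 143, 160, 336)) {
    obs <- gen_fragment_observations(data.frame(position = x, weight = 1),
                                     rmap, length_sd = 0, seed = 1)
    est <- triangulate_sites(obs, rmap)
    expect_equal(est$position[1], x)
    expect_equal(est$error_bp[1], 0)
    expect_identical(est$n_support[1], 5L)
  }
})

test_that("a single reference enzyme leaves the reflection ambiguity unresolved", {
  mc <- minicircle_sequence("336")
  rmap <- restriction_map(mc, "EcoRV")
  obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
                                   rmap, length_sd = 0, seed = 1)
  est <- triangulate_sites(obs, rmap, min_support = 1)
  expect_identical(nrow(est), 2L)
  r <- rmap$entries$position[1]
  mirror <- ((2 * r - 143 - 1) %% 336) + 1
  expect_setequal(round(est$position), c(143, mirror))
  # with the default two-enzyme support requirement nothing passes
  expect_warning(none <- triangulate_sites(obs, rmap), "support")
  expect_identical(nrow(none), 0L)
  expect_error(
    triangulate_sites(data.frame(reference_enzyme = "XmnI", length_bp = 50),
                      rmap), "not in map")
})

test_that("noisy triangulation localises the site within the gel's precision", {
  rmap <- std_map()
  hits <- vapply(1:100, function(s) {
    obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
                                     rmap, length_sd = 5, seed = 2000 + s)
    est <- triangulate_sites(obs, rmap)
    circ_dist_bp(est$position[1], 143, 336)
  }, numeric(1))
  expect_gte(sum(hits <= 8), 95)
})

test_that("the estimation error shrinks roughly as 1/sqrt(candidates)", {
  mc <- minicircle_sequence("336")
  s <- 5
  err_for <- function(enzymes) {
    rmap <- restriction_map(mc, enzymes)
    vapply(1:60, function(seed) {
      obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
                                       rmap, length_sd = s, seed = 3000 + seed)
      est <- triangulate_sites(obs, rmap, min_support = 1)
      circ_dist_bp(est$position[1], 143, 336)
    }, numeric(1))
  }
  rmse <- function(e) sqrt(mean(e^2))
  e2 <- err_for(c("EcoRV", "NdeI"))          # 8 candidates
  e5 <- err_for(c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))  # 20 candidates
  expect_lt(rmse(e5), rmse(e2))
  # true-candidate count rises 4 -> 10; expect sqrt-law scaling within 2x
  ratio <- rmse(e2) / rmse(e5)
  expect_gt(ratio, sqrt(10 / 4) / 2)
  expect_lt(ratio, sqrt(10 / 4) * 2)
})

test_that("band volumes convert to molar fractions via the length correction", {
  expect_equal(site_molar_fractions(c(1, 1), c(100, 300)), c(0.75, 0.25))
  expect_equal(site_molar_fractions(c(100, 300), c(100, 300)), c(0.5, 0.5))
  expect_equal(site_molar_fractions(c(30, 60, 10), c(100, 200, 100)),
               c(0.3, 0.3, 0.1) / 0.7)
  set.seed(9)
  for (i in 1:20) {
    fr <- site_molar_fractions(stats::runif(5), stats::runif(5, 50, 500))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  expect_error(site_molar_fractions(c(0, 0), c(10, 10)), "degenerate")
})
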