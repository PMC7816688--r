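test_that("percentiles bracket the statistic in every cell", {
  set.seed(700)
  freqs <- matrix(runif(40 * 4), 40, 4,
                  dimnames = list(NULL, paste0("i", 1:4)))
  m <- toy_matrix(freqs, depth = 1500)
  f <- apply_filters(m)
  sets <- build_marker_sets(assign_specificity(f))
  q <- quantify_marker_sets(f, sets)
  expect_true(all(q$p5 <= q$value + 1e-9 & q$value <= q$p95 + 1e-9))
  expect_true(all(q$value >= 0 & q$value <= 100))
})

test_that("a pure genotype quantifies at 100 (100-100) on its own marker set", {
  pan <- make_panel(n_genotypes = 2, n_private_snps = 30,
                    reference_length = 20000, seed = 71)
  des <- mixture_design(list(p = c(g1 = 1), q = c(g2 = 1)))
  sim <- simulate_counts(pan, des, sim_config(depth = 2000, error_rate = 0,
                                              seed = 72))
  f <- apply_filters(sim$matrix)
  sets <- build_marker_sets(assign_specificity(f))
  q <- quantify_marker_sets(f, sets)
  cell <- quantification_cell(q, "p", "p")
  expect_equal(cell$value, 100)
  expect_equal(cell$p5, 100)
  expect_equal(cell$p95, 100)
})

test_that("marker-set medians recover designed mixture proportions within binomial error", {
  pan <- make_panel(n_genotypes = 2, n_private_snps = 40,
                    reference_length = 30000, seed = 81)
  des <- mixture_design(list(mixed = c(g1 = 0.7, g2 = 0.3),
                             pure1 = c(g1 = 1), pure2 = c(g2 = 1)))
  sim <- simulate_counts(pan, des, sim_config(depth = 2000, error_rate = 0,
                                              seed = 82))
  f <- apply_filters(sim$matrix)
  sets <- build_marker_sets(assign_specificity(f))
  g1set <- sets[[which(vapply(sets, function(s)
    setequal(s$members, c("mixed", "pure1")), logical(1)))]]
  q <- quantify_marker_sets(f, list(g1set))
  tol <- 3 * sqrt(0.7 * 0.3 / 2000) * 100
  expect_lt(abs(quantification_cell(q, "mixed", g1set$label)$value - 70), tol)
})

test_that("quantification is invariant to scaling all counts", {
  set.seed(90)
  freqs <- matrix(runif(20 * 3, 0.1, 0.9), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  m1 <- toy_matrix(freqs, depth = 300)
  m7 <- snp_matrix(m1$position, m1$ref, m1$counts * 7L,
                   isolates = m1$isolates,
                   reference_length = m1$reference_length)
  f1 <- apply_filters(m1)
  f7 <- apply_filters(m7)
  sets <- build_marker_sets(assign_specificity(f1))
  q1 <- quantify_marker_sets(f1, sets)
  q7 <- quantify_marker_sets(f7, sets)
  expect_equal(q1$value, q7$value, tolerance = 1e-12)
  expect_equal(q1$p5, q7$p5, tolerance = 1e-12)
})

test_that("group collapse arithmetic: BE minus E gives B, clamped at zero", {
  q <- data.frame(isolate = "V34",
                  label = c("BDEFG", "DEFG", "D", "F", "G"),
                  n_snps = c(75, 45, 24, 89, 21), statistic = "median",
                  value = c(67, 28, 0, 0, 0), p5 = 0, p95 = 100)
  class(q) <- c("marker_quantification", "data.frame")
  map <- list(BDEFG = c("B", "D", "E", "F", "G"),
              DEFG = c("D", "E", "F", "G"),
              D = "D", F = "F", G = "G")
  gp <- collapse_groups(q, map)
  expect_equal(gp$pct[gp$group == "B"], 39)
  expect_equal(gp$pct[gp$group == "E"], 28)

  q$value <- c(50, 50, 0, 0, 0)
  gp2 <- collapse_groups(q, map)
  expect_equal(gp2$pct[gp2$group == "B"], 0)

  # subset exceeding superset beyond tolerance warns about heterogeneity
  q$value <- c(30, 50, 0, 0, 0)
  expect_warning(collapse_groups(q, map), "heterogeneity")
})

test_that("a designed three-genotype mixture is recovered through collapse", {
  pan <- make_panel(n_genotypes = 3, n_private_snps = 30,
                    shared_group_spec = list(
                      list(members = c("g1", "g3"), n = 25)),
                    reference_length = 40000, seed = 95)
  # isolate mixing A=g1 30 / B=g2 20 / E=g3 50; pure carriers fix the sets
  des <- mixture_design(list(mix = c(g1 = 0.3, g2 = 0.2, g3 = 0.5),
                             c1 = c(g1 = 1), c2 = c(g2 = 1), c3 = c(g3 = 1)))
  sim <- simulate_counts(pan, des, sim_config(depth = 2000,
                                              error_rate = 0.001, seed = 96))
  f <- apply_filters(sim$matrix)
  sets <- build_marker_sets(assign_specificity(f))
  lab_of <- function(members) names(sets)[vapply(sets, function(s)
    setequal(s$members, members), logical(1))]
  labs <- c(A = lab_of(c("mix", "c1")), B = lab_of(c("mix", "c2")),
            E = lab_of(c("mix", "c3")), AE = lab_of(c("mix", "c1", "c3")))
  q <- quantify_marker_sets(f, sets)
  map <- setNames(list("A", "B", "E", c("A", "E")), labs)
  gp <- collapse_groups(q, map)
  gm <- gp[gp$isolate == "mix", ]
  got <- vapply(c("A", "B", "E"), function(g)
    gm$pct[gm$group == g][1], numeric(1))
  expect_lt(max(abs(got - c(30, 20, 50))), 3 * sqrt(0.25 / 2000) * 100 + 1)
})

test_that("two-genotype isolates show the three-frequency mixture pattern", {
  pan <- make_panel(n_genotypes = 2, n_private_snps = 30,
                    shared_group_spec = list(list(members = c("g1", "g2"),
                                                  n = 20)),
                    reference_length = 30000, seed = 101)
  des <- mixture_design(list(half = c(g1 = 0.5, g2 = 0.5),
                             pure = c(g1 = 1), other = c(g2 = 1)))
  sim <- simulate_counts(pan, des, sim_config(depth = 2000, error_rate = 0,
                                              seed = 102))
  f <- apply_filters(sim$matrix)
  sets <- build_marker_sets(assign_specificity(f))
  pick <- function(members) sets[[which(vapply(sets, function(s)
    setequal(s$members, members), logical(1)))]]
  set_a <- pick(c("half", "pure"))
  set_b <- pick(c("half", "other"))
  set_ab <- pick(c("half", "pure", "other"))
  mp <- mixture_pattern(f, "half", set_a, set_b, set_ab)
  expect_lt(abs(mp$f_a - 0.5), 0.05)
  expect_lt(abs(mp$f_b - 0.5), 0.05)
  expect_gt(mp$f_ab, 0.99)
  mp_pure <- mixture_pattern(f, "pure", set_a, set_b, set_ab)
  expect_gt(mp_pure$f_a, 0.99)
  expect_lt(mp_pure$f_b, 0.01)
  expect_error(mixture_pattern(f, "half", set_a, set_a), "disjoint")
})

test_that("composition cells format and parse back losslessly", {
  cell <- sprintf("%d (%d-%d)", 70, 65, 74)
  expect_equal(unname(parse_composition_cell(cell)), c(70, 65, 74))
  expect_error(parse_composition_cell("garbage"), "unparseable")
})
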