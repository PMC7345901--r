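test_that("interaction space initializes antigens on the unit sphere", {
  cfg <- sim_config(n_antigens = 1e4, lam = 1.618034, seed = 1)
  set.seed(1)
  st <- init_space(cfg)
  norms <- sqrt(rowSums(st$adir^2))
  expect_equal(norms, rep(1, 1e4), tolerance = 1e-12)
  # exponential availability: mean 1/lam within 3 standard errors
  se <- stats::sd(st$antigens$base) / sqrt(1e4)
  expect_lt(abs(mean(st$antigens$base) - 1 / cfg$lam), 3 * se)
  expect_identical(st$antigens$free, st$antigens$base)
  # empty antigen set is allowed and inert
  cfg0 <- sim_config(n_antigens = 0, n_steps = 3, seed = 1)
  st0 <- simulate_repertoire(cfg0)
  expect_true(all(st0$clones$stage %in% c("immature", "naiveB2", "B1")))
  expect_error(sim_config(shape_dim = 1), "shape_dim")
})

test_that("bone-marrow influx seeds uniform naive clones at the r0 shell", {
  cfg <- sim_config(n_antigens = 5, seed = 2)
  set.seed(2)
  st <- init_space(cfg)
  st2 <- bone_marrow_influx(st, cfg, n_new = 0)
  expect_identical(st2$clones, st$clones)
  st3 <- bone_marrow_influx(st, cfg, n_new = 1000)
  expect_equal(nrow(st3$clones), 1000)
  expect_true(all(st3$clones$dg == cfg$r0 * cfg$eps0))
  expect_true(all(st3$clones$r_bonds == cfg$r0))
  expect_true(all(st3$clones$size == 1L))
  # directional uniformity: small mean resultant length at n = 1e4, D = 3
  cfg3 <- sim_config(shape_dim = 3, n_antigens = 1, seed = 3)
  set.seed(3)
  st4 <- bone_marrow_influx(init_space(cfg3), cfg3, n_new = 1e4)
  resultant <- sqrt(sum(colMeans(st4$cdir)^2))
  expect_lt(resultant, 0.05)
})

test_that("engagement probability follows the capped occupancy rule", {
  cfg <- sim_config(n_antigens = 2, seed = 1)
  d <- c(1, rep(0, 7))
  kd <- exp(-cfg$r0 * cfg$eps0 / cfg$ctx$rt)
  # zero free concentration
  expect_equal(engagement_probability(d, cfg$r0 * cfg$eps0, d, 0, cfg), 0)
  # occupancy midpoint at free == K_D
  expect_equal(engagement_probability(d, cfg$r0 * cfg$eps0, d, kd, cfg), 0.5)
  # outside the angular cap: zero regardless of concentration
  far <- c(0, 1, rep(0, 6))
  expect_equal(engagement_probability(d, cfg$r0 * cfg$eps0, far, 100, cfg), 0)
})

test_that("germinal-centre selection is strict and focuses direction", {
  cfg <- sim_config(seed = 1)
  a <- c(1, rep(0, 7))
  # Monte-Carlo: angle to driving antigen decreases in expectation
  set.seed(9)
  n_traj <- 300
  start_angle <- 0.5
  d0 <- cos(start_angle) * a + sin(start_angle) * c(0, 1, rep(0, 6))
  improved <- 0
  for (i in seq_len(n_traj)) {
    clone <- list(r_bonds = 3L, dg = cfg$eps0 * 3 * sum(d0 * a),
                  gc_rounds = 0L)
    dir <- d0
    for (s in 1:10) {
      upd <- germinal_center_step(clone, dir, a, cfg)
      # strict selection: dg never decreases, bonds only grow on acceptance
      expect_gte(upd$dg, clone$dg)
      expect_equal(upd$r_bonds - clone$r_bonds, as.integer(upd$accepted))
      clone <- list(r_bonds = upd$r_bonds, dg = upd$dg,
                    gc_rounds = upd$gc_rounds)
      dir <- upd$dir
    }
    if (acos(sum(dir * a)) < start_angle) improved <- improved + 1
  }
  expect_gt(improved / n_traj, 0.9)
})

test_that("a full step conserves cells and keeps sizes integral", {
  cfg <- small_sim_config()
  st <- simulate_repertoire(cfg)
  led <- st$ledger
  expect_equal(nrow(led), cfg$n_steps)
  # conservation: total(t) = total(t-1) + influx + divisions - deaths - apoptosis
  prev <- c(0, led$total[-nrow(led)])
  expect_equal(led$total,
               prev + led$influx + led$divisions - led$deaths - led$apoptosis)
  expect_true(all(st$clones$size >= 1))
  expect_true(all(st$clones$size == round(st$clones$size)))
  expect_true(all(st$clones$size <= cfg$max_clone_size))
})

test_that("zero rates freeze the repertoire except for antigen relaxation", {
  cfg <- sim_config(n_antigens = 5, influx_per_step = 0, division_rate = 0,
                    death_rate = c(immature = 0, naiveB2 = 0, GC = 0,
                                   MBC = 0, LLPC = 0, B1 = 0),
                    n_steps = 1, seed = 4)
  set.seed(4)
  st <- init_space(cfg)
  st <- bone_marrow_influx(st, cfg, n_new = 50)
  before <- st$clones[c("id", "r_bonds", "size")]
  st2 <- sim_step(st, cfg)
  # no influx, no division, no death: same clones and sizes
  expect_equal(st2$clones[c("id", "r_bonds", "size")]
               [order(st2$clones$id), ],
               before[order(before$id), ], ignore_attr = TRUE)
})

test_that("radial monotonicity holds along every lineage", {
  cfg <- small_sim_config()
  st <- simulate_repertoire(cfg)
  # energy never decreases from the birth shell (itself above the CLP origin)
  expect_true(all(st$clones$dg >= st$clones$dg_birth))
  expect_true(all(st$clones$dg_birth > 0))
})

test_that("B1 clones are stable and never enter germinal centres", {
  cfg <- small_sim_config()
  st <- simulate_repertoire(cfg)
  b1 <- st$clones[st$clones$stage == "B1", ]
  expect_gt(nrow(b1), 0)
  expect_true(all(b1$dg == cfg$r0 * cfg$eps0))
  expect_true(all(b1$r_bonds == cfg$r0))
  expect_true(all(is.na(b1$subnetwork)))
})

test_that("retraction leaves one plasma-cell hub per subnetwork above its memory", {
  cfg <- small_sim_config()
  st <- simulate_repertoire(cfg)
  cl <- st$clones
  retracted <- cl[cl$stage %in% c("MBC", "LLPC"), ]
  expect_gt(sum(retracted$stage == "LLPC"), 0)
  for (s in unique(retracted$subnetwork)) {
    members <- retracted[retracted$subnetwork == s, ]
    expect_equal(sum(members$stage == "LLPC"), 1)
    llpc_dg <- members$dg[members$stage == "LLPC"]
    expect_true(all(members$dg[members$stage == "MBC"] <= llpc_dg))
  }
  # no-op on a state without GC clones
  set.seed(1)
  empty <- init_space(cfg)
  expect_identical(retract(empty, cfg)$clones, empty$clones)
})

test_that("antigen relaxation follows the geometric closed form", {
  cfg <- sim_config(n_antigens = 1, rho = 0.5, seed = 6)
  set.seed(6)
  st <- init_space(cfg)
  base <- st$antigens$base
  # no secreting clones: free stays at base
  st2 <- update_antigen(st, cfg)
  expect_identical(st2$antigens$free, base)
  # one perfectly aligned LLPC with K_D below base
  dg <- 30
  st$clones <- data.frame(id = 1L, stage = "LLPC", r_bonds = 12L, dg = dg,
                          dg_birth = dg, size = 1L, parent = NA_integer_,
                          subnetwork = 1L, gc_rounds = 0L, birth = 0L)
  st$cdir <- st$adir[1, , drop = FALSE]
  kd <- exp(-dg / cfg$ctx$rt)
  n_rel <- ceiling(log(0.01) / log(1 - cfg$rho))
  for (i in seq_len(n_rel)) st <- update_antigen(st, cfg)
  expected <- kd + (base - kd) * (1 - cfg$rho)^n_rel
  expect_equal(st$antigens$free, expected, tolerance = 1e-12)
  expect_lt(abs(st$antigens$free - kd) / (base - kd), 0.01)
  expect_lte(st$antigens$free, base)
})

test_that("simulation is reproducible and its CSV export is byte-identical", {
  cfg <- sim_config(n_antigens = 10, n_steps = 40, seed = 99)
  s1 <- simulate_repertoire(cfg)
  s2 <- simulate_repertoire(cfg)
  expect_identical(s1$clones, s2$clones)
  expect_identical(s1$antigens, s2$antigens)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s1$clones, f1, row.names = FALSE)
  write.csv(s2$clones, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("summaries partition the repertoire and report regulation", {
  cfg <- small_sim_config()
  st <- simulate_repertoire(cfg)
  summ <- summarize_repertoire(st, cfg)
  expect_equal(sum(summ$shell_counts), nrow(st$clones))
  expect_equal(sum(summ$stage_counts), nrow(st$clones))
  expect_equal(summ$clone_table$ksys,
               exp((st$clones$dg - mean(st$clones$dg)) / cfg$ctx$rt))
  # empty repertoire gives an all-zero summary
  set.seed(1)
  s0 <- summarize_repertoire(init_space(cfg), cfg)
  expect_true(all(s0$stage_counts == 0))
  expect_equal(nrow(s0$clone_table), 0)
})
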