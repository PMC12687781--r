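test_that("native contacts respect the cutoff boundary and role symmetry", {
  cx <- fixture_complex(3)
  expect_gt(nrow(native_contacts(cx)), 0)
  # two chains far apart: not a complex
  apart <- move_ligand(cx, diag(3), c(100, 0, 0))
  expect_error(native_contacts(apart), "no inter-chain contacts")
  # boundary: single CB-CB pair at 4.9 in, 5.1 out
  d <- flowdock:::.residue_min_dist(receptor_chain(cx), ligand_chain(cx))
  con <- native_contacts(cx, cutoff = 5.0)
  expect_true(all(d[con] < 5.0))
  not_con <- which(d >= 5.0, arr.ind = TRUE)
  expect_false(any(paste(con[, 1], con[, 2]) %in%
                     paste(not_con[, 1], not_con[, 2])))
  # swapping roles transposes the contact pairs
  sw <- cx; sw$receptor_index <- 2L; sw$ligand_index <- 1L
  con_sw <- native_contacts(sw)
  expect_setequal(paste(con[, 1], con[, 2]), paste(con_sw[, 2], con_sw[, 1]))
})

test_that("dockq identities, closed-form decoy, and strict thresholds", {
  cx <- fixture_complex(4)
  perfect <- dockq(cx, cx)
  expect_equal(perfect$fnat, 1)
  expect_lt(perfect$irmsd, 1e-9)
  expect_lt(perfect$lrmsd, 1e-9)
  expect_equal(perfect$dockq, 1.0, tolerance = 1e-9)
  expect_identical(perfect$quality, "high")

  # closed form: fnat 0.5, irmsd 1.5, lrmsd 8.5 -> (0.5 + 0.5 + 0.5)/3 = 0.5
  dec <- dockq_from_components(0.5, 1.5, 8.5)
  expect_equal(dec$dockq, 0.5, tolerance = 1e-12)
  expect_identical(dec$quality, "medium")

  # strict inequalities at the class boundaries: a score exactly at a
  # threshold falls in the lower class
  expect_identical(dockq_quality(0.23), "incorrect")
  expect_identical(dockq_quality(0.23 + 1e-12), "acceptable")
  expect_identical(dockq_quality(0.49), "acceptable")
  expect_identical(dockq_quality(0.49 + 1e-12), "medium")
  expect_identical(dockq_quality(0.80), "medium")
  expect_identical(dockq_quality(0.80 + 1e-12), "high")
  expect_identical(dockq_quality(0.0), "incorrect")

  # rigid transform of the model leaves dockq unchanged
  moved <- transform_complex(cx, random_rotation(5), c(4, 4, 4))
  same <- dockq(moved, cx)
  expect_equal(same$dockq, 1.0, tolerance = 1e-9)
  expect_error(dockq(fixture_complex(4, 21, 18), cx), "mismatch")
})

test_that("ps-iRMSD ignores rigid subunit motion and reports planted deformation", {
  cx <- fixture_complex(6)
  expect_equal(unname(ps_irmsd(cx, cx, cx)), c(0, 0))
  # rigid ligand motion: individual alignment removes it entirely
  moved <- move_ligand(cx, random_rotation(2), c(8, -3, 5))
  v <- ps_irmsd(moved, cx, cx)
  expect_lt(v["ligand"], 1e-9)
  expect_lt(v["receptor"], 1e-9)
  # a planted 1 A zig-zag deformation of the ligand interface (alternating
  # +/- 1 A along x, not removable by any rigid motion) reads back ~1 A
  ifr <- flowdock:::.interface_residues(cx)
  def <- cx
  li <- def$ligand_index
  ch <- def$chains[[li]]
  for (k in seq_along(ifr$ligand)) {
    ri <- ifr$ligand[k]
    ch$coords[ri, , 1] <- ch$coords[ri, , 1] + c(1, -1)[1 + k %% 2]
  }
  def$chains[[li]] <- ch
  v2 <- ps_irmsd(def, cx, cx)
  expect_gt(v2[["ligand"]], 0.5)
  expect_lt(v2[["ligand"]], 1.4)
  expect_lt(v2[["receptor"]], 1e-9)
  # interface-alignment variant exists and also reports the deformation
  v3 <- ps_irmsd(def, cx, cx, align = "interface")
  expect_gt(v3[["ligand"]], 0.4)
})

test_that("success rates are monotone with bootstrap CIs; ranking sorted", {
  cx <- fixture_complex(3)
  good <- cx
  bad <- move_ligand(cx, random_rotation(7), c(40, 0, 0))
  ps <- prediction_set("t1", list(bad, good, bad), c(0.2, 0.9, 0.5), cx)
  expect_equal(ps$confidence, c(0.9, 0.5, 0.2))
  expect_equal(ps$dockq[1], 1.0, tolerance = 1e-9)

  sets <- list(ps, ps, ps)
  sr <- success_rates(sets, ks = c(1L, 2L), n_boot = 500L)
  expect_equal(sr$top1$rate, 1)
  expect_equal(unname(sr$top1$ci), c(1, 1))
  expect_gte(sr$oracle$rate, sr$top2$rate)
  expect_gte(sr$top2$rate, sr$top1$rate)
  # k larger than the set size is clamped with a warning
  expect_warning(success_rates(sets, ks = 5L, n_boot = 100L), "clamped")

  # bootstrap CI width matches the binomial closed form at p = 0.5
  set.seed(33)
  succ <- stats::rbinom(180, 1, 0.5)
  ci <- flowdock:::.boot_ci(succ, n_boot = 10000L)
  width <- diff(ci)
  closed <- 2 * 1.96 * sqrt(0.25 / 180)
  expect_lt(abs(width - closed) / closed, 0.2)
})

test_that("one-sided Wilcoxon detects direction and handles ties", {
  set.seed(8)
  y <- stats::runif(20, 1, 2)
  x <- y - stats::runif(20, 0.2, 0.5)   # x uniformly smaller
  expect_lt(paired_one_sided_test(x, y), 0.01)
  # reversed direction is not significant
  expect_gt(paired_one_sided_test(y, x), 0.5)
  expect_warning(p <- paired_one_sided_test(y, y), "zero")
  expect_equal(p, 1)
  expect_error(paired_one_sided_test(1:3, 3:1))
})

test_that("bootstrap CI coverage is nominal over synthetic replicates", {
  # moved to test-acceptance.R at full scale; quick sanity here
  set.seed(21)
  hit <- 0L
  for (r in 1:100) {
    succ <- stats::rbinom(60, 1, 0.4)
    ci <- flowdock:::.boot_ci(succ, n_boot = 800L)
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) hit <- hit + 1L
  }
  expect_gt(hit, 85)
})
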