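test_that("residue metrics reproduce hand-computed confusion values", {
  perfect <- residue_metrics("SSLL", "SSLL")
  expect_equal(perfect$q2, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f_score, 1)
  # TP=3, FP=1, FN=1, TN=5: spec=75, sens=75, F=0.75, Q2=80,
  # MCC = (3*5-1*1)/sqrt(4*4*6*6) = 14/24
  pred <- c(rep("S", 4), rep("L", 6))
  truth <- c(rep("S", 3), "L", "S", rep("L", 5))
  m <- residue_metrics(pred, truth)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 5)
  expect_equal(m$specificity, 75)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$f_score, 0.75)
  expect_equal(m$q2, 80)
  expect_equal(m$mcc, 14 / 24)
  # all-negative prediction: zero sensitivity, MCC 0 by convention
  deg <- residue_metrics("LLLL", "SLSL")
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$mcc, 0)
  expect_error(residue_metrics("SL", "SLL"), "lengths differ")
})

test_that("strand metrics match by overlap with single-use truth strands", {
  a <- cbind(start = c(1L, 11L), end = c(8L, 18L))
  expect_equal(strand_metrics(a, a)$mcc, 1)
  expect_equal(strand_metrics(a, a)$f_score, 1)
  # shift by one residue keeps the match under the 50% rule
  shifted <- a + 1L
  m <- strand_metrics(shifted, a)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  # 7 of 8 matched plus 1 spurious: spec = sens = 87.5
  truth <- cbind(start = seq(1L, 71L, 10L), end = seq(8L, 78L, 10L))
  pred <- rbind(truth[1:7, ], c(90L, 97L))
  m2 <- strand_metrics(pred, truth)
  expect_equal(m2$specificity, 87.5)
  expect_equal(m2$sensitivity, 87.5)
  expect_equal(m2$mcc, 0.875) # TN-free limit: sqrt(precision * recall)
  # an overlap below half the shorter strand does not match
  off <- cbind(start = 5L, end = 12L)
  expect_equal(strand_metrics(off, cbind(start = 1L, end = 8L))$tp, 1L)
  expect_equal(strand_metrics(off, cbind(start = 1L, end = 8L),
                              overlap_rule = 0.6)$tp, 0L)
})

test_that("loop mutation respects rate, sites and reproducibility", {
  fix <- make_barrel_fixture(fixture_spec(seed = 4), id = "mut")
  N <- fix$sequence$N
  same <- mutate_loops(fix, rate = 0, seed = 1)
  expect_equal(same$residues, fix$sequence$residues)
  mut <- mutate_loops(fix, rate = 0.05, seed = 1)
  diffs <- which(mut$residues != fix$sequence$residues)
  expect_length(diffs, floor(0.05 * N))
  expect_true(all(fix$states[diffs] == "L"))
  # reproducible under the seed, different under another
  expect_equal(mutate_loops(fix, rate = 0.05, seed = 1)$residues,
               mut$residues)
  expect_false(identical(mutate_loops(fix, rate = 0.05, seed = 2)$residues,
                         mut$residues))
  # requesting more mutations than loop sites mutates all of them
  tiny <- labeled_structure(protein_sequence("t", "GIDIDIDIDG"),
                            "LSSSSSSSSL")
  expect_warning(all_mut <- mutate_loops(tiny, rate = 0.9, seed = 3),
                 "mutable loop positions")
  expect_true(all(all_mut$residues[2:9] == tiny$sequence$residues[2:9]))
})

test_that("classification accepts a planted barrel and rejects non-TMB", {
  cfg <- fixture_config()
  tab <- fixture_table()
  fix <- make_barrel_fixture(fixture_spec(seed = 7), id = "tmb")
  res <- classify(fix$sequence, tab, cfg)
  expect_equal(res$decision, "TMB")
  expect_equal(res$best_structure$n, 8L)
  expect_equal(res$best_structure$S, attr(fix, "truth")$S)
  expect_gte(res$per_strand_criterion, cfg$classify_threshold)
  expect_equal(nrow(res$scanned), nrow(enumerate_nS(fix$sequence$N, cfg)))
  # a sequence with no filter-passing segment is rejected outright
  polar <- protein_sequence("polar", strrep("DQEN", 40))
  res2 <- classify(polar, tab, cfg)
  expect_equal(res2$decision, "non-TMB")
  expect_null(res2$best_structure)
  # threshold dominance: an unreachable threshold flips the decision
  res3 <- classify(fix$sequence, tab,
                   fixture_config(classify_threshold = 1e6))
  expect_equal(res3$decision, "non-TMB")
  expect_false(is.null(res3$best_structure))
})

test_that("permutation landscape covers all permutations consistently", {
  g <- make_random_graph(12, seed = 7)
  perms <- list(barrel_permutation(1:4),
                barrel_permutation(c(1, 3, 2, 4)),
                barrel_permutation(c(1, 4, 3, 2)))
  land <- permutation_landscape(g, 4, 2, perms, window = 0.02)
  expect_equal(nrow(land), length(perms))
  idr <- which(land$sigma == "1,2,3,4")
  ref <- fold_barrel(g, 4, 2)
  if (ref$feasible) {
    expect_equal(land$energy[idr], ref$energy, tolerance = 1e-9)
  } else {
    expect_true(is.na(land$energy[idr]))
  }
  # window = 0 keeps only global minimizers
  land0 <- permutation_landscape(g, 4, 2, perms, window = 0)
  if (any(!is.na(land0$energy))) {
    expect_equal(sum(land0$in_window),
                 sum(land0$energy == min(land0$energy, na.rm = TRUE),
                     na.rm = TRUE))
  }
})

test_that("fold stability under loop mutation keeps strand-level F high", {
  cfg <- fixture_config()
  tab <- fixture_table()
  fix <- make_barrel_fixture(fixture_spec(seed = 13), id = "stab")
  g0 <- build_fold_graph(fix$sequence, tab, cfg)
  st0 <- fold_barrel(g0, 8, 8)
  expect_true(st0$feasible)
  mut <- mutate_loops(fix, rate = 0.05, seed = 21)
  g1 <- build_fold_graph(mut, tab, cfg)
  st1 <- fold_barrel(g1, 8, 8)
  expect_true(st1$feasible)
  m <- strand_metrics(st1, st0)
  expect_gte(m$f_score, 0.85)
})
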