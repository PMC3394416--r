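test_that("left/right insertion neighbors match the worked permutation", {
  sig <- c(1, 2, 5, 4, 3, 6)
  lr <- vapply(1:6, function(k) left_right(sig, k), integer(2))
  expect_equal(lr["left", ], c(6L, 1L, 4L, 5L, 2L, 3L))
  expect_equal(lr["right", ], c(2L, 5L, 6L, 3L, 4L, 1L))
  # identity permutation: neighbors are the sequence neighbors with wrap
  for (n in c(4L, 7L)) {
    id <- seq_len(n)
    expect_equal(left_right(id, 1L), c(left = n, right = 2L))
    expect_equal(left_right(id, n), c(left = n - 1L, right = 1L))
    for (k in 2:(n - 1L)) {
      expect_equal(left_right(id, k), c(left = k - 1L, right = k + 1L))
    }
  }
  expect_error(left_right(sig, 7L), "out of")
  expect_error(barrel_permutation(c(2, 1, 3)), "sigma\\(1\\)")
})

test_that("active index sets match the worked permutation", {
  sig <- c(1, 2, 5, 4, 3, 6)
  expect_equal(conf_set(sig, 1), 1L)
  expect_equal(conf_set(sig, 2), c(1L, 2L))
  expect_equal(conf_set(sig, 3), c(1L, 2L, 3L))
  expect_equal(conf_set(sig, 4), c(1L, 2L, 3L, 4L))
  expect_equal(conf_set(sig, 5), c(1L, 3L, 5L))
  expect_equal(conf_set(sig, 6), 6L)
  # identity: the first strand stays active for barrel closure
  for (k in 2:5) expect_equal(conf_set(seq_len(6), k), c(1L, k))
  expect_equal(conf_set(seq_len(6), 6), 6L)
})

test_that("adjacency closure resolves deferred loops at the right level", {
  sig <- c(1, 2, 5, 4, 3, 6)
  cl5 <- adjacency_closure(sig, 5)
  expect_equal(cl5$delta, c(2L, 4L))
  expect_true(2L %in% cl5$delta) # strand-2/3 loop resolves when 5 is laid
  expect_equal(adjacency_closure(sig, 4)$A, c(1L, 3L))
  expect_equal(cl5$A, c(1L, 2L, 3L, 4L))
  # identity: each loop resolves immediately
  for (k in 2:6) {
    expect_equal(adjacency_closure(seq_len(6), k)$delta, k - 1L)
  }
})

test_that("circular permutation enumeration is complete and duplicate-free", {
  p5 <- enumerate_circular_permutations(5)
  expect_length(p5, factorial(4))
  keys <- vapply(p5, function(p) paste(p$sigma, collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_length(enumerate_circular_permutations(2), 1L)
  expect_true(all(vapply(p5, function(p) p$sigma[1] == 1L, logical(1))))
})

test_that("greek key permutations include the printed motifs", {
  gk <- greek_key_permutations(6)
  keys <- vapply(gk, function(p) paste(p$sigma, collapse = ","),
                 character(1))
  expect_true("1,2,3,6,5,4" %in% keys) # motif appended after identity run
  expect_true("1,2,5,4,3,6" %in% keys) # the worked example
  expect_true("1,4,3,2,5,6" %in% keys) # motif at the reference position
  expect_true(paste(1:6, collapse = ",") %in% keys)
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("sheet solver agrees with the oracle on seeded graphs", {
  for (seed in 1:20) {
    g <- make_random_graph(10, seed = seed)
    for (S in c(0L, 2L)) {
      a <- fold_sheet(g, 3, S)
      b <- brute_force_fold(g, 3, S, closed = FALSE)
      expect_equal(a$feasible, b$feasible)
      if (a$feasible) {
        expect_equal(a$criterion, b$criterion, tolerance = 1e-12)
        expect_equal(sum(a$relative_shears), S)
        expect_length(a$relative_shears, 2L)
      }
    }
  }
})

test_that("barrel solver agrees with the oracle and closes the barrel", {
  for (seed in 1:20) {
    g <- make_random_graph(10, seed = seed)
    for (S in c(0L, 2L, 4L)) {
      a <- fold_barrel(g, 4, S)
      b <- brute_force_fold(g, 4, S, closed = TRUE)
      expect_equal(a$feasible, b$feasible)
      if (a$feasible) {
        expect_equal(a$criterion, b$criterion, tolerance = 1e-12)
        expect_equal(sum(a$relative_shears), S)
        expect_length(a$relative_shears, 4L) # wrap pair included
        # traceback re-scores to the DP criterion exactly
        sc <- score_structure(g, a$vids, S)
        expect_true(sc$feasible)
        expect_equal(sc$criterion, a$criterion, tolerance = 1e-9)
      }
    }
  }
})

test_that("a unique feasible chain is returned verbatim", {
  g <- make_random_graph(5, seed = 99, p_edge = 1)
  # restrict to one start and one end so few chains exist
  b <- brute_force_fold(g, 3, 1, closed = FALSE)
  a <- fold_sheet(g, 3, 1)
  expect_equal(a$feasible, b$feasible)
  if (a$feasible) expect_equal(a$vids, b$vids)
})

test_that("shifting all intrinsic energies shifts the criterion by n*c", {
  g1 <- make_random_graph(9, seed = 3)
  g2 <- g1
  g2$vertices$e_intr <- g1$vertices$e_intr + 2
  g2$cache <- new.env(parent = emptyenv())
  a1 <- fold_sheet(g1, 3, 1)
  a2 <- fold_sheet(g2, 3, 1)
  if (a1$feasible) {
    expect_equal(a2$criterion, a1$criterion - 3 * 2, tolerance = 1e-9)
    expect_equal(a1$vids, a2$vids)
  }
})

test_that("permuted solver reduces to the identity barrel", {
  for (seed in c(2, 5, 9)) {
    g <- make_random_graph(10, seed = seed)
    for (S in c(0L, 3L)) {
      a <- fold_barrel(g, 4, S)
      p <- fold_barrel_permuted(g, 4, S, 1:4)
      expect_equal(a$feasible, p$feasible)
      if (a$feasible) {
        expect_equal(p$criterion, a$criterion, tolerance = 1e-12)
      }
    }
  }
})

test_that("permuted solver agrees with the oracle for greek keys", {
  gks <- list(c(1, 2, 3, 6, 5, 4), c(1, 2, 5, 4, 3, 6),
              c(1, 4, 3, 2, 5, 6))
  for (seed in 1:8) {
    g <- make_random_graph(12, seed = seed + 100)
    for (sig in gks) {
      for (S in c(0L, 3L)) {
        a <- fold_barrel_permuted(g, 6, S, sig)
        b <- brute_force_fold(g, 6, S, sigma = sig, closed = TRUE)
        expect_equal(a$feasible, b$feasible)
        if (a$feasible) {
          expect_equal(a$criterion, b$criterion, tolerance = 1e-12)
          sc <- score_structure(g, a$vids, S, sig, TRUE)
          expect_true(sc$feasible)
          expect_equal(sc$criterion, a$criterion, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("DP state counts respect the conf-size bound", {
  for (seed in c(11, 12)) {
    g <- make_random_graph(12, seed = seed)
    for (sig in list(1:6, c(1, 2, 5, 4, 3, 6))) {
      p <- barrel_permutation(sig)
      maxconf <- max(vapply(1:6, function(k) length(conf_set(p, k)),
                            integer(1)))
      st <- fold_barrel_permuted(g, 6, 2, p)
      expect_lte(attr(st, "max_states"),
                 g$n_vert^maxconf)
    }
  }
})

test_that("exhaustive shear branching matches its oracle", {
  for (seed in 1:5) {
    g <- make_random_graph(8, seed = seed, s_values = -2:2,
                           exhaustive_shear = TRUE)
    for (S in c(1L, 3L)) {
      a <- fold_barrel(g, 3, S)
      b <- brute_force_fold(g, 3, S, closed = TRUE)
      expect_equal(a$feasible, b$feasible)
      if (a$feasible) {
        expect_equal(a$criterion, b$criterion, tolerance = 1e-12)
        expect_equal(sum(a$relative_shears), S)
      }
    }
  }
})

test_that("infeasible problems return explicit no-solution results", {
  g <- make_random_graph(6, seed = 1)
  st <- fold_barrel(g, 4, 100L)
  expect_false(st$feasible)
  expect_match(st$reason, "shear|no path")
  bf <- brute_force_fold(g, 4, 100L)
  expect_false(bf$feasible)
  expect_error(brute_force_fold(make_random_graph(16, seed = 1), 4, 0,
                                guard = 12L), "guard")
  expect_error(fold_barrel_permuted(g, 4, 0, c(1, 3, 2, 4) + 0), NA)
  expect_error(fold_barrel_permuted(g, 4, 0, c(2, 1, 3, 4)), "sigma")
})
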