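toy_table <- function() {
  # one all-strand AAAA and one all-other poly-G carrier, no smoothing
  # surprises: pseudocount 1
  train <- list(
    labeled_structure(protein_sequence("s", "AAAA"), "SSSS"),
    labeled_structure(protein_sequence("o", "GGGG"), "LLLL")
  )
  train_block_table(train, l = 3L, pseudocount = 1)
}

test_that("training counts windows fully inside conformation runs", {
  tab <- toy_table()
  expect_equal(unname(tab$counts$strand["AAA"]), 2)
  expect_true(is.na(tab$counts$other["AAA"]))
  # smoothed cell: raw + pseudocount
  expect_equal(barrelfold:::block_count(tab, "strand", "AAA"), 3)
  expect_equal(barrelfold:::block_count(tab, "other", "AAA"), 1)
  # windows straddling a run boundary are not counted
  mixed <- train_block_table(list(
    labeled_structure(protein_sequence("m", "AAAGGG"), "SSSLLL")), l = 3L)
  expect_equal(unname(mixed$counts$strand["AAA"]), 1)
  expect_equal(unname(mixed$counts$other["GGG"]), 1)
  expect_false("AAG" %in% names(mixed$counts$strand))
  expect_error(train_block_table(list()), "empty")
  expect_error(train_block_table(list(toy_table()), l = 0), "block length")
})

test_that("marginal identities hold exactly after smoothing", {
  tab <- fixture_table()
  raw <- vapply(tab$counts, sum, numeric(1))
  expect_equal(unname(tab$f_tau),
               unname(raw + tab$pseudocount * 20^tab$l))
  # f_.,. equals the sum over conformations of f_tau,.
  expect_equal(sum(tab$f_tau),
               sum(raw) + 2 * tab$pseudocount * 20^tab$l)
})

test_that("block information and preference follow the log-ratio forms", {
  # hand-built table: f_strand,AAA = 8, f_other,AAA = 2, totals 10/10
  tab <- structure(list(
    l = 3L, pseudocount = 0,
    counts = list(strand = c(AAA = 8, CCC = 2), other = c(AAA = 2, CCC = 8)),
    f_tau = c(strand = 10, other = 10), n_blocks = 20^3
  ), class = "block_table")
  expect_equal(block_info(tab, "strand", "AAA"), log(1.6))
  expect_equal(block_preference(tab, "AAA"), log(4))
  # no influence when the block is distributed like the marginals
  even <- structure(list(
    l = 3L, pseudocount = 0,
    counts = list(strand = c(AAA = 5), other = c(AAA = 5)),
    f_tau = c(strand = 50, other = 50), n_blocks = 20^3
  ), class = "block_table")
  expect_equal(block_info(even, "strand", "AAA"), 0)
  # scale invariance: doubling every count leaves I unchanged
  dbl <- tab
  dbl$counts <- lapply(tab$counts, `*`, 2)
  dbl$f_tau <- tab$f_tau * 2
  expect_equal(block_info(dbl, "strand", "AAA"),
               block_info(tab, "strand", "AAA"))
  # antisymmetry of the preference
  expect_equal(block_preference(tab, "CCC", tau = "other"),
               -block_preference(tab, "CCC", tau = "strand"))
})

test_that("segment score matches its closed form and is monotone in rho", {
  tab <- toy_table()
  seg <- "AAAA" # two AAA blocks
  pref <- block_preference(tab, "AAA")
  expect_equal(segment_score(tab, seg, rho = 1), 2 * pref)
  expect_equal(segment_score(tab, seg, rho = 2 / 3),
               2 * pref - log(2 / 3) * 2)
  # zero-preference segments gain exactly the -log rho bonus per block
  neutral <- structure(list(
    l = 3L, pseudocount = 1, counts = list(strand = numeric(0), other = numeric(0)),
    f_tau = c(strand = 8000, other = 8000), n_blocks = 8000
  ), class = "block_table")
  expect_equal(segment_score(neutral, "MKVLMK", rho = 2 / 3),
               -4 * log(2 / 3))
  expect_gt(segment_score(neutral, "MKVLMK", rho = 2 / 3), 0)
  # decreasing rho never decreases the score
  scores <- vapply(c(2 / 3, 1 / 2, 1 / 3), function(r)
    segment_score(tab, seg, rho = r), numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_error(segment_score(tab, "AA"), "shorter than block length")
})

test_that("side averages separate the two faces of a segment", {
  s <- protein_sequence("amph", "IAIAIA")
  sa <- side_averages(s, 1, 6)
  expect_equal(unname(sa["H_odd"]), 4.5)
  expect_equal(unname(sa["H_even"]), 1.8)
  # homopolymer: both sides identical
  hp <- side_averages(protein_sequence("h", "GGGGG"), 1, 5)
  expect_equal(unname(hp["H_even"]), unname(hp["H_odd"]))
  # parity is absolute: a shifted window keeps residues on their sides
  sa2 <- side_averages(s, 2, 5)
  expect_equal(unname(sa2["H_odd"]), 4.5)
  expect_equal(unname(sa2["H_even"]), 1.8)
  expect_error(side_averages(s, 3, 3), "single-residue")
  expect_error(side_averages(s, 0, 4), "invalid")
})

test_that("candidate segments honor hydrophobicity bounds and facing", {
  cfg <- fixture_config()
  tab <- fixture_table()
  # both side averages at -3 fail the hydrophobic-side bound
  polar <- protein_sequence("p", strrep("D", 12))
  expect_equal(nrow(candidate_segments(polar, tab, cfg)), 0L)
  # a planted amphipathic strand is found with the correct facing
  fix <- make_barrel_fixture(fixture_spec(seed = 5), id = "c")
  cand <- candidate_segments(fix$sequence, tab, cfg)
  truth <- attr(fix, "truth")$strands
  hit <- merge(cand, truth, by.x = c("start", "end"),
               by.y = c("start", "end"))
  expect_equal(nrow(hit), nrow(truth))
  expect_equal(hit$facing.x, hit$facing.y)
  # output is sorted and id-independent
  expect_true(!is.unsorted(cand$start))
  fix2 <- fix$sequence
  fix2$id <- "renamed"
  expect_equal(candidate_segments(fix2, tab, cfg), cand)
})

test_that("block table serialization round-trips", {
  tab <- toy_table()
  path <- tempfile(fileext = ".tsv")
  write_block_table(tab, path)
  back <- read_block_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$l, tab$l)
  expect_equal(back$f_tau, tab$f_tau)
})

test_that("exponentiated preferences normalize against the other class", {
  tab <- fixture_table()
  aa <- names(barrelfold:::KD_SCALE)
  blocks <- as.vector(outer(as.vector(outer(aa, aa, paste0)), aa, paste0))
  expect_length(blocks, 20^3)
  f_s <- barrelfold:::block_count(tab, "strand", blocks) / tab$f_tau["strand"]
  f_o <- barrelfold:::block_count(tab, "other", blocks) / tab$f_tau["other"]
  # sum_r exp(preference) * f_other,r / f_other,. recovers sum_r f_strand
  expect_equal(sum(exp(block_preference(tab, blocks)) * f_o), 1)
  expect_equal(sum(f_s), 1)
})
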