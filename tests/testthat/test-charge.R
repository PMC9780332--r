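test_that("residue charges follow the integer side-chain model", {
  expect_identical(residue_charge("K"), 1L)
  expect_identical(residue_charge("R"), 1L)
  expect_identical(residue_charge("D"), -1L)
  expect_identical(residue_charge("E"), -1L)
  expect_identical(residue_charge("G"), 0L)
  expect_identical(residue_charge("H"), 0L)  # histidine neutral
  expect_error(residue_charge("X"), class = "invalid_residue")
  expect_error(residue_charge("k"), class = "invalid_residue")
})

test_that("net charge of the tag unit and multiples", {
  expect_identical(net_charge("GGSKKRKKR"), 6L)
  expect_identical(net_charge(tag_sequence(3)), 18L)  # 12 K + 6 R
  expect_identical(nchar(tag_sequence(3)), 27L)
  expect_error(net_charge(""), class = "empty_input")
})

test_that("net charge matches the letter-count oracle on random sequences", {
  set.seed(11)
  for (k in 1:1000) {
    s <- random_aa_seq(sample(5:80, 1))
    expect_identical(net_charge(s), as.integer(oracle_net_charge(s)))
  }
})

test_that("net charge is additive over concatenation", {
  set.seed(12)
  for (k in 1:50) {
    a <- random_aa_seq(sample(3:40, 1))
    b <- random_aa_seq(sample(3:40, 1))
    expect_identical(net_charge(paste0(a, b)),
                     net_charge(a) + net_charge(b))
  }
})

test_that("non-canonical residues error by default, warn when permissive", {
  expect_error(net_charge("GGXKK"), class = "invalid_residue")
  expect_error(net_charge("GGXKK"), "position 3")
  expect_warning(ch <- net_charge("GGXKK", permissive = TRUE),
                 class = "noncanonical_residue")
  expect_identical(ch, 2L)
})

test_that("fusion charge arithmetic reproduces the engineered variants", {
  expect_identical(fusion_charge(-7, 2, 1), 6L)   # sfGFP-tag2
  expect_identical(fusion_charge(+6, 3, 0), 24L)  # GFP(+6)-tag3
  expect_identical(fusion_charge(0, 0, 0), 0L)
  expect_error(fusion_charge(0, -1, 0), class = "invalid_argument")
})

test_that("the 3 domains x 3 tags library spans 0..+24 in +6 steps", {
  # sfGFP(-7) variants carry the +1 lysine linker to stay charge-equivalent
  charges <- c(
    vapply(1:3, function(n) fusion_charge(-7, n, 1), 0L),
    vapply(1:3, function(n) fusion_charge(0, n, 0), 0L),
    vapply(1:3, function(n) fusion_charge(6, n, 0), 0L)
  )
  expect_length(charges, 9L)
  expect_setequal(unique(charges), seq(0L, 24L, by = 6L))
})

test_that("tag designer hits the transient threshold exactly", {
  d <- design_tag(-7, "transient")
  expect_identical(d$n_repeats, 2L)
  expect_identical(d$linker_lysines, 1L)
  expect_identical(d$predicted_fusion_charge, 6L)
  expect_identical(d$behavior_class, "transient")

  d0 <- design_tag(0, "transient")
  expect_identical(d0$n_repeats, 1L)
  expect_identical(d0$linker_lysines, 0L)
  expect_identical(d0$predicted_fusion_charge, 6L)

  expect_error(design_tag(+7, "transient"), class = "infeasible_design")
})

test_that("tag designer lands on the smallest achievable persistent charge", {
  d <- design_tag(+6, "persistent")
  expect_identical(d$n_repeats, 1L)
  expect_identical(d$linker_lysines, 0L)
  expect_identical(d$predicted_fusion_charge, 12L)
  expect_identical(d$behavior_class, "persistent")

  # domain charge -2, target +12: needs +14 = 2 repeats + 2 lysines
  d2 <- design_tag(-2, "persistent")
  expect_identical(d2$predicted_fusion_charge, 12L)
  expect_identical(d2$n_repeats, 2L)
  expect_identical(d2$linker_lysines, 2L)

  # already above target: stays put
  d3 <- design_tag(+15, "persistent")
  expect_identical(d3$predicted_fusion_charge, 15L)
  expect_identical(d3$n_repeats, 0L)

  expect_error(design_tag(0, "persistent", persistent_target = 6),
               class = "invalid_argument")
})

test_that("designed fusion peptide round-trips to the predicted charge", {
  set.seed(13)
  for (k in 1:40) {
    dom <- random_aa_seq(sample(20:120, 1))
    mode <- sample(c("transient", "persistent"), 1)
    d <- tryCatch(design_tag(dom, mode),
                  condentag_error = function(e) NULL)
    if (is.null(d)) {
      expect_gt(net_charge(dom), 6)  # only legitimate failure mode
      next
    }
    expect_identical(net_charge(d$fusion_peptide),
                     d$predicted_fusion_charge)
    expect_identical(nchar(d$fusion_peptide),
                     nchar(dom) + d$linker_lysines + 9L * d$n_repeats)
  }
})

test_that("charge distribution counts windows exactly", {
  recs <- c(neg7 = "DDDDDDD", zero = "GGG", pos6 = "GGSKKRKKR")
  d <- proteome_charge_distribution(recs)
  expect_equal(fraction_in_window(d, -6, 6), 2 / 3)
  expect_equal(fraction_in_window(d, -Inf, Inf), 1)
  # degenerate single-record distribution jumps 0 -> 1 at +6
  d1 <- proteome_charge_distribution(c(tag = "GGSKKRKKR"))
  expect_identical(d1$cdf$charge, 6L)
  expect_identical(d1$cdf$cumulative_fraction, 1)
})

test_that("charge CDF is a valid non-decreasing distribution", {
  set.seed(14)
  recs <- vapply(1:60, function(i) random_aa_seq(sample(10:60, 1)), "")
  d <- proteome_charge_distribution(recs)
  expect_true(all(diff(d$cdf$cumulative_fraction) >= 0))
  expect_equal(d$cdf$cumulative_fraction[nrow(d$cdf)], 1)
  # window fractions are monotone in window width
  f1 <- fraction_in_window(d, -2, 2)
  f2 <- fraction_in_window(d, -6, 6)
  f3 <- fraction_in_window(d, -20, 20)
  expect_true(f1 <= f2 && f2 <= f3)
})

test_that("invalid records are skipped with a warning and counted", {
  expect_warning(
    d <- proteome_charge_distribution(c(a = "KKKK", b = "KXK", c = "DD")),
    class = "invalid_records_skipped")
  expect_identical(d$n_skipped, 1L)
  expect_length(d$charges, 2L)
  expect_error(proteome_charge_distribution(character(0)),
               class = "empty_input")
})

test_that("FASTA reading handles wrapped multi-record files", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">a first", "GGSKK", "RKKR", ">b", "DDEE"), tf)
  recs <- read_fasta(tf)
  expect_identical(unname(recs), c("GGSKKRKKR", "DDEE"))
  expect_identical(names(recs), c("a", "b"))
  expect_identical(net_charge(recs[["a"]]), 6L)
  tab <- write_charge_table(recs, tempfile(fileext = ".csv"))
  expect_identical(tab$net_charge, c(6L, -4L))
})

test_that("the bundled sfGFP sequence computes to -7", {
  sf <- read_fasta(system.file("extdata", "sfGFP.fasta",
                               package = "condentag"))
  expect_identical(net_charge(sf[[1]]), -7L)
  expect_identical(nchar(sf[[1]]), 238L)
})
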