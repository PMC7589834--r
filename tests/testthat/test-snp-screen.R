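# Consensus nsSNP screen: parsing, cutoffs, consensus and agreement.

test_that("substitution strings parse and validate", {
  s <- parse_substitution("G1050V")
  expect_equal(s, list(wild = "G", position = 1050L, mutant = "V"))
  expect_equal(parse_substitution("S1067C")$position, 1067L)
  expect_error(parse_substitution("G1050G"), "identical")
  expect_error(parse_substitution("X123A"), "alphabet error")
  expect_error(parse_substitution("1050GV"), "parse error")
})

test_that("the packaged score table reproduces the published consensus", {
  tab <- read_score_table(table1_path())
  expect_equal(nrow(tab), 4)

  calls <- apply_cutoffs(tab)
  # S741C: 8 deleterious calls, MAPP is the single no-call
  s741 <- calls["rs762112742", ]
  expect_equal(sum(s741 == "deleterious"), 8)
  expect_equal(names(s741)[s741 == "no_call"], "MAPP")
  # Y793C: MAPP and SNP&GO missing -> 7 deleterious, 2 no-calls
  y793 <- calls["rs1461682152", ]
  expect_equal(sum(y793 == "deleterious"), 7)
  expect_setequal(names(y793)[y793 == "no_call"], c("MAPP", "SNP_GO"))

  cs <- consensus(tab, min_tools = 7)
  expect_true(all(cs$is_consensus_deleterious))
  expect_setequal(cs$substitution, c("S741C", "Y793C", "G1050V", "S1067C"))
  expect_equal(min(cs$n_deleterious), 7)
  # sorted by count descending: the 8-tool variant leads
  expect_equal(cs$substitution[1], "S741C")

  # at nine required tools no row with a missing score can qualify
  cs9 <- consensus(tab, min_tools = 9)
  expect_lte(sum(cs9$is_consensus_deleterious), 1)
  expect_equal(sum(cs9$is_consensus_deleterious), 0)
})

test_that("cutoff boundaries are applied exactly as written", {
  row <- function(sift = 0.5, imut = 0, panther = 0) data.frame(
    rs_id = "rs1", substitution = "A10V", SIFT = sift,
    PolyPhen2_HumDiv = 0.5, PolyPhen2_HumVar = 0.5, MAPP = "N",
    PANTHER = panther, SNP_GO = 0.1, PhD_SNP = 0.1, PredictSNP = "N",
    PROVEAN = 0, I_Mutant = imut, stringsAsFactors = FALSE)
  # SIFT <= 0.05 is inclusive
  expect_equal(unname(apply_cutoffs(row(sift = 0.05))[1, "SIFT"]),
               "deleterious")
  expect_equal(unname(apply_cutoffs(row(sift = 0.051))[1, "SIFT"]),
               "neutral")
  # I-Mutant < -0.5 is exclusive
  expect_equal(unname(apply_cutoffs(row(imut = -0.5))[1, "I_Mutant"]),
               "neutral")
  expect_equal(unname(apply_cutoffs(row(imut = -0.501))[1, "I_Mutant"]),
               "deleterious")
  # PANTHER >= 0.5 is inclusive
  expect_equal(unname(apply_cutoffs(row(panther = 0.5))[1, "PANTHER"]),
               "deleterious")
  # PolyPhen-2 requires both models jointly
  r <- row(); r$PolyPhen2_HumDiv <- 0.95
  expect_equal(unname(apply_cutoffs(r)[1, "PolyPhen2"]), "neutral")
  r$PolyPhen2_HumVar <- 0.95
  expect_equal(unname(apply_cutoffs(r)[1, "PolyPhen2"]), "deleterious")
  # a non-numeric score in a numeric column is a named error
  r2 <- row(); r2$PROVEAN <- "oops"
  expect_error(apply_cutoffs(r2), "PROVEAN")
})

test_that("missing scores are no-calls and never count as deleterious", {
  tab <- generate_score_table(60, planted_deleterious = 1:30, seed = 51)
  base <- consensus(tab)
  # blanking a tool can only lower the count, never raise it
  tab_blank <- tab; tab_blank$PANTHER <- NA
  blanked <- consensus(tab_blank)
  m <- match(blanked$rs_id, base$rs_id)
  expect_true(all(blanked$n_deleterious <= base$n_deleterious[m]))
  expect_true(all(base$n_deleterious[m] - blanked$n_deleterious <= 1))

  # an empty score row yields zero deleterious calls
  empty <- tab[1, ]
  empty[, -(1:2)] <- NA
  expect_equal(consensus(empty)$n_deleterious, 0L)
  expect_false(consensus(empty)$is_consensus_deleterious)
})

test_that("tightening any threshold never increases the deleterious count", {
  tab <- generate_score_table(120, planted_deleterious = 1:40, seed = 52)
  for (sift_cut in c(0.05, 0.03, 0.01)) {
    cuts <- default_cutoffs()
    cuts$SIFT$threshold <- sift_cut
    n <- sum(consensus(tab, cuts)$n_deleterious)
    if (exists("prev_n")) expect_lte(n, prev_n)
    prev_n <- n
  }
  for (prov_cut in c(-2.5, -4, -6)) {
    cuts <- default_cutoffs()
    cuts$PROVEAN$threshold <- prov_cut
    n <- sum(consensus(tab, cuts)$n_deleterious)
    if (exists("prev_p")) expect_lte(n, prev_p)
    prev_p <- n
  }
})

test_that("tool agreement is a symmetric phi matrix with sane nulls", {
  # perfectly concordant tools
  tab <- generate_score_table(50, planted_deleterious = 1:25,
                              pass_prob_deleterious = 1,
                              pass_prob_neutral = 0, seed = 53)
  phi <- tool_agreement_matrix(tab)
  expect_equal(unname(diag(phi)), rep(1, 9))
  expect_equal(phi, t(phi))
  expect_equal(unname(phi["SIFT", "PROVEAN"]), 1, tolerance = 1e-12)

  # independent random calls: near-zero off-diagonal agreement
  null_tab <- generate_score_table(500, planted_deleterious = integer(),
                                   pass_prob_neutral = 0.5, seed = 54)
  phi0 <- tool_agreement_matrix(null_tab)
  off <- phi0[upper.tri(phi0)]
  expect_lt(max(abs(off)), 0.15)
})
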