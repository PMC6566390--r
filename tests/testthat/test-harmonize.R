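test_that("an outcome record on the other allele is re-signed", {
  expo <- tibble::tibble(snp = "rs10741657", effect_allele = "A",
                         other_allele = "G", eaf = 0.4,
                         beta = 0.031, se = 0.0022)
  outc <- tibble::tibble(snp = "rs10741657", effect_allele = "G",
                         other_allele = "A", eaf = 0.6,
                         beta = -0.005, se = 0.004)
  set <- harmonize(expo, outc)
  expect_equal(set$beta_outcome, 0.005)
  expect_true(set$orientation_flipped)
  expect_equal(mr_audit(set)$action, "flipped")
})

test_that("the DS fixture harmonizes with no flips and a retained palindromic SNP", {
  set <- mr_fixture("vitd_ds")
  expect_equal(nrow(set), 6)
  expect_false(any(set$orientation_flipped))
  i <- which(set$snp == "rs8018720")
  expect_true(set$palindromic[i])
  expect_false(any(set$palindromic[-i]))
  audit <- mr_audit(set)
  expect_equal(audit$reason[audit$snp == "rs8018720"],
               "palindromic_retained")
})

test_that("variants absent from one side are excluded and logged once", {
  expo <- tibble::tibble(
    snp = c("rs1", "rs99999"), effect_allele = c("A", "T"),
    other_allele = c("G", "C"), eaf = c(0.3, 0.4),
    beta = c(0.05, 0.02), se = c(0.01, 0.01))
  outc <- tibble::tibble(
    snp = c("rs1", "rs777"), effect_allele = c("A", "T"),
    other_allele = c("G", "C"), eaf = c(0.3, 0.2),
    beta = c(0.01, 0.01), se = c(0.01, 0.01))
  set <- harmonize(expo, outc)
  expect_equal(set$snp, "rs1")
  audit <- mr_audit(set)
  expect_equal(sum(audit$snp == "rs99999"), 1)
  expect_equal(audit$reason[audit$snp == "rs99999"], "not_in_outcome")
  expect_equal(audit$reason[audit$snp == "rs777"], "not_in_exposure")
})

test_that("palindromic handling follows the frequency window", {
  expo <- tibble::tibble(
    snp = c("rs_amb", "rs_clear"), effect_allele = c("A", "C"),
    other_allele = c("T", "G"), eaf = c(0.52, 0.82),
    beta = c(0.02, 0.03), se = c(0.01, 0.01))
  outc <- tibble::tibble(
    snp = c("rs_amb", "rs_clear"), effect_allele = c("A", "C"),
    other_allele = c("T", "G"), eaf = c(0.52, 0.82),
    beta = c(0.01, 0.01), se = c(0.01, 0.01))
  set <- harmonize(expo, outc)
  expect_equal(set$snp, "rs_clear")
  audit <- mr_audit(set)
  expect_equal(audit$reason[audit$snp == "rs_amb"],
               "palindromic_ambiguous_eaf")
  # widening the window drops the clear one too, then nothing survives
  expect_error(harmonize(expo, outc, palindromic_eaf_window = 0.45),
               "no instruments survived")
  # drop_palindromic drops regardless of frequency
  expect_error(harmonize(expo, outc, drop_palindromic = TRUE),
               "no instruments survived")
})

test_that("a discordant palindromic frequency flips the outcome", {
  expo <- tibble::tibble(snp = "rs_p", effect_allele = "C",
                         other_allele = "G", eaf = 0.82,
                         beta = 0.03, se = 0.01)
  outc <- tibble::tibble(snp = "rs_p", effect_allele = "C",
                         other_allele = "G", eaf = 0.18,
                         beta = 0.02, se = 0.01)
  set <- harmonize(expo, outc)
  expect_equal(set$beta_outcome, -0.02)
  expect_equal(mr_audit(set)$reason, "palindromic_eaf_flip")
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  expo <- tibble::tibble(snp = c("rs1", "rs2"),
                         effect_allele = c("A", "A"),
                         other_allele = c("G", "G"), eaf = 0.3,
                         beta = 0.05, se = 0.01)
  outc <- tibble::tibble(snp = c("rs1", "rs2"),
                         effect_allele = c("A", "A"),
                         other_allele = c("G", "C"), eaf = 0.3,
                         beta = 0.01, se = 0.01)
  set <- harmonize(expo, outc)
  expect_equal(set$snp, "rs1")
  audit <- mr_audit(set)
  expect_equal(audit$reason[audit$snp == "rs2"], "allele_mismatch")
})

test_that("strand-complement records align without sign change", {
  expo <- tibble::tibble(snp = "rs1", effect_allele = "A",
                         other_allele = "G", eaf = 0.3,
                         beta = 0.05, se = 0.01)
  outc <- tibble::tibble(snp = "rs1", effect_allele = "T",
                         other_allele = "C", eaf = 0.3,
                         beta = 0.02, se = 0.01)
  set <- harmonize(expo, outc)
  expect_equal(set$beta_outcome, 0.02)
  expect_equal(mr_audit(set)$reason, "strand_complement")
})

test_that("harmonize + orient is invariant under allele-label swaps", {
  base_expo <- vitd_exposure_table <- tibble::tibble(
    snp = paste0("rs", 1:5),
    effect_allele = c("A", "T", "C", "G", "A"),
    other_allele = c("G", "C", "T", "T", "C"),
    eaf = c(0.3, 0.7, 0.2, 0.6, 0.45),
    beta = c(0.05, -0.03, 0.02, -0.04, 0.01), se = 0.01)
  outc <- dplyr::mutate(base_expo, beta = c(0.01, 0.02, -0.01, 0.005, 0),
                        se = 0.02)
  reference <- orient_exposure_increasing(harmonize(base_expo, outc))
  for (seed in 1:5) {
    swap <- withr::with_seed(seed, sample(c(TRUE, FALSE), 5, TRUE))
    swapped <- base_expo
    swapped$effect_allele[swap] <- base_expo$other_allele[swap]
    swapped$other_allele[swap] <- base_expo$effect_allele[swap]
    swapped$beta[swap] <- -base_expo$beta[swap]
    swapped$eaf[swap] <- 1 - base_expo$eaf[swap]
    res <- orient_exposure_increasing(harmonize(swapped, outc))
    cols <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome", "eaf", "palindromic")
    expect_equal(tibble::as_tibble(res)[cols],
                 tibble::as_tibble(reference)[cols], ignore_attr = TRUE)
  }
})

test_that("orientation is idempotent and flags toggled", {
  set <- mr_fixture("vitd_ds")
  once <- orient_exposure_increasing(set)
  expect_true(all(once$beta_exposure >= 0))
  i <- match(c("rs3755967", "rs8018720"), once$snp)
  expect_equal(once$beta_exposure[i], c(0.089, 0.017))
  expect_equal(once$beta_outcome[i], c(0.001, -0.001))
  expect_true(all(once$orientation_flipped[i]))
  twice <- orient_exposure_increasing(once)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("a zero exposure effect survives orientation with a warning", {
  x <- tibble::tibble(snp = "rs0", beta_exposure = 0, se_exposure = 0.01,
                      beta_outcome = 0.01, se_outcome = 0.01)
  expect_warning(res <- orient_exposure_increasing(x), "rs0")
  expect_equal(res$beta_outcome, 0.01)
})

test_that("every input variant appears exactly once in the audit log", {
  sim <- simulate_two_sample(n_snps = 8, allele_model = TRUE, seed = 3)
  set <- harmonize(sim$exposure, sim$outcome)
  audit <- mr_audit(set)
  expect_equal(sort(audit$snp), sort(sim$exposure$snp))
  expect_equal(anyDuplicated(audit$snp), 0)
  expect_equal(nrow(set) + sum(audit$action == "dropped"),
               length(intersect(sim$exposure$snp, sim$outcome$snp)))
})
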