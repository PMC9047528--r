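test_that("top-N accuracy counts the first matching rank", {
  # truth found at rank 3 of the single record
  preds <- list(c("CC", "CCC", "CCO"))
  expect_equal(top_n_accuracy(preds, "CCO", Ns = c(1, 3, 10)),
               c(top1 = 0, top3 = 1, top10 = 1))
  # all rank-1 predictions correct
  preds2 <- list("CCO", "CC(=O)O.CCO")
  truths2 <- c("OCC", "CCO.CC(=O)O")
  expect_equal(unname(top_n_accuracy(preds2, truths2, Ns = c(1, 5))),
               c(1, 1))
})

test_that("top-N fractions equal brute-force counts on a 10-record fixture", {
  mols <- c("CCO", "CCC", "CCN", "CCCC", "CC(=O)O", "CCOCC", "C", "CC",
            "CCCCC", "COC")
  truth_rank <- c(1, 1, 2, 4, Inf, 3, 1, Inf, 10, 5)
  preds <- lapply(seq_along(mols), function(i) {
    # valid fillers that can never match (extra molecule in the multiset)
    p <- vapply(1:10, function(k) paste0(strrep("C", k), ".", mols[i]),
                character(1))
    if (is.finite(truth_rank[i])) p[truth_rank[i]] <- mols[i]
    p
  })
  got <- top_n_accuracy(preds, mols, Ns = c(1, 3, 5, 10))
  for (n in c(1, 3, 5, 10))
    expect_equal(unname(got[paste0("top", n)]),
                 sum(truth_rank <= n) / 10)    # hand-countable
  expect_error(top_n_accuracy(preds[1:3], mols[1:2]), "equal length")
  expect_error(top_n_accuracy(list(character(0)), "CCO"),
               "at least one prediction")
})

test_that("per-class accuracy restricts to classes and skips empty ones", {
  preds <- list("CCO", "CCC", "CCN", "CCCC")
  truths <- c("CCO", "CCC", "CC", "CC")
  cls <- c(1L, 1L, 2L, 2L)
  got <- per_class_accuracy(preds, truths, cls, N = 1)
  expect_equal(got, c(class_1 = 1.0, class_2 = 0.0))
  expect_false("class_3" %in% names(got))     # absent, not zero
  # single class reduces to overall top-N accuracy
  one <- per_class_accuracy(preds[1:2], truths[1:2], c(5L, 5L), N = 1)
  expect_equal(unname(one), unname(top_n_accuracy(preds[1:2], truths[1:2],
                                                  Ns = 1)))
  expect_error(per_class_accuracy(preds, truths, c(1L, 1L, 2L, 99L), N = 1,
                                  n_classes = 10L), "unknown class")
})

test_that("per-class fractions equal brute-force counts on a 20-record fixture", {
  set.seed(31)
  truths <- rep(c("CCO", "CCC", "CCCC", "CC"), 5)
  cls <- rep(1:3, length.out = 20)
  hit <- runif(20) < 0.5
  preds <- lapply(1:20, function(i) if (hit[i]) truths[i] else "C")
  got <- per_class_accuracy(preds, truths, cls, N = 1)
  for (k in 1:3)
    expect_equal(unname(got[paste0("class_", k)]),
                 sum(hit & cls == k) / sum(cls == k))
})

test_that("invalidity rate counts grammar failures at rank 1", {
  expect_equal(invalidity_rate(c("CCO", "C((C"))$overall, 0.5)
  expect_equal(invalidity_rate(c("CCO", "CC", "c1ccccc1"))$overall, 0)
  # planted fixture: 40 strings, 7 corrupted
  valid <- vapply(toy_records(40), `[[`, character(1), "product")
  bad_idx <- c(3, 9, 14, 22, 28, 33, 40)
  strings <- valid
  for (i in seq_along(bad_idx))
    strings[bad_idx[i]] <- mutate_to_invalid(valid[bad_idx[i]], seed = i)
  got <- invalidity_rate(strings, class_ids = rep(1:4, each = 10))
  expect_equal(got$overall, 7 / 40)
  expect_equal(got$overall, 0.175)
  # validity + invalidity rates are complementary by construction
  expect_equal(got$overall + mean(is_valid_smiles(strings)), 1)
  expect_equal(sum(got$per_class * 10), 7)
})

test_that("ring-system classification agrees with the frozen perception oracle", {
  fx <- read_fixture("ring_oracle.tsv")
  expect_equal(nrow(fx), 30L)
  got <- vapply(fx$smiles, classify_ring_system, character(1),
                USE.NAMES = FALSE)
  expect_identical(got, fx$ring_class)
  # the three canonical exemplars, by name
  expect_equal(classify_ring_system("C1CCC2(CC1)CCCC2"), "spiro")
  expect_equal(classify_ring_system("C1CC2CCC1C2"), "bridged")
  expect_equal(classify_ring_system("C1CCC2CCCCC2C1"), "fused")
  expect_error(classify_ring_system("C1CC"), "invalid")
})

test_that("substructure matching agrees with the frozen SMARTS oracle", {
  fx <- read_fixture("substructure_oracle.tsv")
  reg <- default_failure_registry()
  pat <- function(cat) reg$value[reg$category == cat]
  expect_identical(vapply(fx$smiles, has_substructure, logical(1),
                          pattern = pat("R-Boc"), USE.NAMES = FALSE), fx$boc)
  expect_identical(vapply(fx$smiles, has_substructure, logical(1),
                          pattern = pat("R-CF3"), USE.NAMES = FALSE), fx$cf3)
  expect_identical(vapply(fx$smiles, has_substructure, logical(1),
                          pattern = pat("R-tBu"), USE.NAMES = FALSE), fx$tbu)
})

test_that("failure categorization applies Boc-over-tBu precedence and totals", {
  failed <- data.frame(
    record_id = as.character(1:4),
    truth = c("CC(C)(C)OC(=O)NC",      # Boc (not tBu: precedence)
              "OC(=O)C(F)(F)F",        # CF3
              "CC(C)(C)c1ccccc1",      # tBu only
              "CCO"))                  # none
  got <- categorize_failures(failed)
  counts <- setNames(got$count, got$category)
  expect_equal(unname(counts["R-Boc"]), 1)
  expect_equal(unname(counts["R-CF3"]), 1)
  expect_equal(unname(counts["R-tBu"]), 1)
  expect_equal(unname(counts["Total"]),
               sum(counts[names(counts) != "Total"]))
  expect_equal(got$rate[got$category == "R-Boc"], 1 / 4)
  # a molecule in several categories counts once per category in the total
  multi <- data.frame(record_id = "1",
                      truth = "CC(C)(C)OC(=O)NCc1ccc(C(F)(F)F)cc1")
  gm <- categorize_failures(multi)
  expect_equal(gm$count[gm$category == "Total"], 2)  # Boc + CF3
  expect_error(categorize_failures(data.frame(record_id = "1", truth = "C"),
                                   registry = data.frame(
                                     category = "bad", kind = "pattern",
                                     value = "C((C", precedence_over = "")),
               "malformed pattern")
})

test_that("ring categories feed failure categorization", {
  failed <- data.frame(record_id = as.character(1:3),
                       truth = c("C1CCC2(CC1)CCCC2.O",   # spiro
                                 "C1CC2CCC1C2",          # bridged
                                 "c1ccc2ccccc2c1"))      # fused
  got <- categorize_failures(failed)
  counts <- setNames(got$count, got$category)
  expect_equal(unname(counts[c("R-spiro", "R-bridged", "R-fused")]),
               c(1, 1, 1))
})

test_that("corrected accuracy adds plausible annotations without double counting", {
  ann <- data.frame(record_id = sprintf("r%d", 1:10), plausible = TRUE,
                    type = rep("hydrolysis", 10))
  got <- corrected_accuracy(100, 50, ann)
  expect_equal(got$corrected_fraction, 0.60)
  expect_equal(got$corrected_count, 60)
  # zero annotations: corrected equals exact
  none <- corrected_accuracy(100, 50, NULL)
  expect_equal(none$corrected_fraction, none$exact_fraction)
  # corrected >= exact always
  expect_gte(got$corrected_fraction, got$exact_fraction)
  # annotating an exact-matching record is double counting
  expect_error(corrected_accuracy(100, 50, ann, matched_ids = "r3"),
               "double counting")
  expect_error(corrected_accuracy(100, 50, rbind(ann, ann[1, ])),
               "duplicate")
  # breakdown total row sums the per-type counts
  bd <- got$breakdown
  expect_equal(bd$count[bd$type == "Total"],
               sum(bd$count[bd$type != "Total"]))
})

test_that("the rate-sum form reproduces the headline true-accuracy arithmetic", {
  # exact 54.1% + plausible types summing to 10.5% -> 64.6%
  expect_equal(true_accuracy_rate_sum(54.1, c(0.2, 1.0, 2.5, 0.7, 2.4, 1.4,
                                              2.3)), 64.6)
  got <- corrected_accuracy(1000, 541,
                            data.frame(record_id = sprintf("a%d", 1:105),
                                       plausible = TRUE,
                                       type = "other"))
  expect_equal(got$rate_sum_pct, 64.6)
})

test_that("evaluation reports are internally consistent", {
  preds <- list(c("CCO", "CC"), c("C", "CC"), c("C((C", "CCN"))
  truths <- c("OCC", "CC", "CCN")
  rep_ <- evaluate_predictions(preds, truths, class_ids = c(1L, 1L, 2L),
                               Ns = c(1L, 2L))
  expect_equal(unname(rep_$per_n["top1"]), 1 / 3)
  expect_equal(unname(rep_$per_n["top2"]), 1)
  # accuracy is non-decreasing in N, overall and per class
  expect_true(all(diff(rep_$per_n) >= 0))
  for (r in rownames(rep_$per_class))
    expect_true(all(diff(rep_$per_class[r, ]) >= 0))
  expect_equal(rep_$invalidity$overall, 1 / 3)
  tf <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, tf)
  js <- jsonlite::read_json(tf)
  expect_equal(js$n_test, 3L)
  expect_equal(js$top_n$top1, 1 / 3, tolerance = 1e-12)
})
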