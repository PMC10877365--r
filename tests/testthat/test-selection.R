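test_that("subset-count arithmetic matches enumeration", {
  expect_equal(powerset_size(19), 524288)
  expect_equal(powerset_size(0), 1)
  expect_equal(powerset_size(3), 8)
  expect_equal(stepwise_eval_count(19), 190)
  expect_equal(stepwise_eval_count(1), 1)
  # p = 4: enumerate the candidates a forward search generates
  chans <- c("a", "b", "c", "d")
  n_cand <- 0L
  current <- character(0)
  for (k in 1:4) {
    n_cand <- n_cand + length(setdiff(chans, current))
    current <- c(current, setdiff(chans, current)[1])
  }
  expect_equal(stepwise_eval_count(4), n_cand)
})

test_that("forward selection is nested, exhaustive and correctly counted", {
  chans <- standard_montage()$channels
  sc <- counting_scorer(function(s) length(s))   # monotone scorer
  tr <- forward_select(chans, sc)
  expect_equal(attr(sc, "count")(), 190)
  expect_equal(tr$total_evaluations, 190)
  # nested chain increasing by exactly one channel, covering 1..19
  sizes <- vapply(tr$chain, length, integer(1))
  expect_equal(sizes, 1:19)
  for (k in 2:19)
    expect_true(all(tr$chain[[k - 1]] %in% tr$chain[[k]]))
  expect_setequal(tr$chain[[19]], chans)
  expect_equal(tr$best_per_cardinality$size, 1:19)
  # monotone scorer ties at every step: tie rule picks the earliest
  # remaining channel in canonical order
  expect_equal(tr$chain[[1]], "Fp1")
  expect_equal(tr$chain[[2]], c("Fp1", "Fp2"))
})

test_that("forward selection finds a planted dominant channel first", {
  chans <- standard_montage()$channels
  tr <- forward_select(chans, function(s) as.numeric("T7" %in% s))
  expect_equal(tr$chain[[1]], "T7")
  # truncated search stops early but keeps the pick
  tr1 <- forward_select(chans, function(s) as.numeric("T7" %in% s),
                        max_steps = 1)
  expect_length(tr1$chain, 1L)
  expect_equal(tr1$chain[[1]], "T7")
})

test_that("backward selection mirrors forward and keeps the vital channel", {
  chans <- standard_montage()$channels
  sc <- counting_scorer(function(s) -length(s))
  tr <- backward_select(chans, sc)
  expect_equal(attr(sc, "count")(), 190)
  expect_equal(tr$total_evaluations, 190)
  sizes <- vapply(tr$chain, length, integer(1))
  expect_equal(sizes, 19:1)
  for (k in 2:19)
    expect_true(all(tr$chain[[k]] %in% tr$chain[[k - 1]]))
  # a scorer punishing the loss of P4 keeps P4 to the end
  keeper <- backward_select(chans, function(s)
    as.numeric("P4" %in% s) + length(s) * 1e-4)
  expect_equal(keeper$chain[[19]], "P4")
  # deterministic tie handling: identical runs give identical traces
  tr2 <- backward_select(chans, function(s) -length(s))
  expect_identical(tr$chain, tr2$chain)
})

test_that("forward and backward agree on an unambiguous best singleton", {
  chans <- c("Fp1", "T7", "O2", "Pz")
  strength <- c(Fp1 = 0.1, T7 = 0.9, O2 = 0.3, Pz = 0.5)
  scorer <- function(s) max(strength[s])
  fw <- forward_select(chans, scorer)
  bw <- backward_select(chans, scorer)
  expect_equal(fw$chain[[1]], "T7")
  expect_equal(bw$chain[[length(chans)]], "T7")
})

test_that("scorer failures abort with the offending subset named", {
  chans <- c("Fp1", "T7")
  expect_error(forward_select(chans, function(s) NA_real_), "scorer failed")
  expect_error(backward_select(chans, function(s) NaN), "scorer failed")
})

test_that("selection traces serialise to bitmask records and back", {
  chans <- standard_montage()$channels
  tr <- forward_select(chans, function(s) length(s), max_steps = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_trace(tr, path)
  recs <- read_selection_trace(path)
  expect_equal(nrow(recs), 19 + 18 + 17)
  expect_true(all(nchar(recs$mask) == 19))
  expect_equal(sum(recs$chosen), 3L)
  # bitmask of the first chosen subset has exactly one set bit
  first <- recs$mask[recs$chosen & recs$step == 1]
  expect_equal(sum(strsplit(first, "")[[1]] == "1"), 1L)
})

test_that("recovery rate scores traces against the planted set", {
  chans <- standard_montage()$channels
  aligned <- lapply(1:5, function(i)
    forward_select(chans, function(s) as.numeric("T7" %in% s),
                   max_steps = 1))
  expect_equal(recovery_rate(aligned, c("T7", "P3", "Pz")), 1.0)
  miss <- forward_select(chans, function(s) as.numeric("O2" %in% s),
                         max_steps = 1)
  expect_equal(recovery_rate(c(aligned, list(miss)), c("T7", "P3", "Pz")),
               5 / 6)
  expect_error(recovery_rate(list(), "T7"), "no traces")
  expect_error(recovery_rate(aligned, "T7", top_m = 2), "top_m")
})

test_that("random scorers pick planted channels at the chance rate", {
  # 1 informative of 19, top_m = 1: expected rate 1/19 under a scorer
  # carrying no information (random iid scores)
  chans <- standard_montage()$channels
  set.seed(31)
  picks <- vapply(1:400, function(i) {
    tr <- forward_select(chans, function(s) runif(1), max_steps = 1)
    tr$chain[[1]] == "T7"
  }, logical(1))
  expect_gt(binom.test(sum(picks), 400, 1 / 19)$p.value, 0.01)
})

test_that("surrogate scorer ranks planted channels above noise channels", {
  ws <- tiny_cohort_ws(n_per_class = 8L, sf = 32, duration = c(20, 24),
                       effect = 3, informative = c("T7", "T8"), seed = 3L)
  scorer <- make_surrogate_scorer(ws, seed = 3L)
  informative <- mean(c(scorer("T7"), scorer("T8")))
  noise <- mean(c(scorer("Fp1"), scorer("O2")))
  expect_gt(informative, noise)
  # scores are valid f1 values and deterministic
  expect_true(informative >= 0 && informative <= 1)
  expect_equal(scorer("T7"), scorer("T7"))
})
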