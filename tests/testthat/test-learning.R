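test_that("depression follows the floored update rule", {
  w <- synapse_weights("x", w0 = 5, delta = 1)
  w <- update_weights(w, 2, "reward")
  expect_equal(w$w_avoid, 3)
  expect_equal(w$w_approach, 5)
  w2 <- synapse_weights("x", w0 = 1, delta = 1)
  w2 <- update_weights(w2, 2, "reward")
  expect_equal(w2$w_avoid, 0)  # floor
  expect_error(update_weights(w, -1, "reward"), ">= 0")
  expect_error(synapse_weights("x", delta = 0), "> 0")
})

test_that("reliable synapses saturate within normal training, unreliable do not", {
  # reliable: responds 10 of 12 trials with amplitude 1; unreliable: 2 of 12
  # with amplitude 0.3; delta 0.2
  w <- synapse_weights(c("rel", "unrel"), w0 = 1, delta = 0.2)
  resp <- matrix(0, 12, 2)
  resp[1:10, 1] <- 1
  resp[1:2, 2] <- 0.3
  w <- update_weights(w, resp, "reward")
  expect_equal(w$w_avoid[1], 0)
  expect_equal(w$w_avoid[2], 1 - 2 * 0.2 * 0.3)
  # weights are non-increasing in trial count
  w_more <- update_weights(w, resp, "reward")
  expect_true(all(w_more$w_avoid <= w$w_avoid))
  expect_true(all(w_more$w_avoid >= 0))
})

test_that("simplified saturation zeroes exactly the stated classes", {
  counts <- matrix(c(5, 2, 0, 6,
                     1, 5, 2, 0), 4, 2)
  tab <- table_from_counts(counts, n_trials = 6)
  cfg <- training_config(simplified_saturation = TRUE)
  wn <- train_association(tab, c(1, 2), cfg, "normal")
  # odor A rewarded: reliable-for-A cells (1 and 4) lose their avoid weight
  expect_equal(wn$w_avoid, c(0, 1, 1, 0))
  # odor B punished: reliable-for-B cells (2) lose their approach weight
  expect_equal(wn$w_approach, c(1, 0, 1, 1))
  we <- train_association(tab, c(1, 2), cfg, "extended")
  expect_equal(we$w_avoid, c(0, 0, 1, 0))       # + unreliable for A (2)
  expect_equal(we$w_approach, c(0, 0, 0, 1))    # + unreliable for B (1, 3)
})

test_that("full training with a large learning rate converges to the simplified mode", {
  tens <- generate_responses(generator_config("custom", n_cells = 60,
                                              n_odors = 2), seed = 71)
  tab <- classify_cells(detect_significant(tens))
  cfg <- training_config(simplified_saturation = FALSE)
  w_full <- train_association(tab, c(1, 2), cfg, "extended",
                              weights = synapse_weights(
                                tab$cell[tab$odor == tab$odor[1]],
                                w0 = 1, delta = 100),
                              seed = 72)
  w_simp <- train_association(tab, c(1, 2),
                              training_config(simplified_saturation = TRUE),
                              "extended")
  a <- tab[tab$odor == tab$odor[1], ]
  responsive <- a$p_response > 0
  # over 100 trials every responsive cell fires at least once w.h.p.
  expect_equal(w_full$w_avoid[responsive], w_simp$w_avoid[responsive])
})

test_that("discrimination scores follow the response-probability-weighted rule", {
  tab <- table_from_counts(matrix(c(2, 0), 1, 2), n_trials = 6)
  w <- synapse_weights("cell1")
  w$w_approach <- 2; w$w_avoid <- 4
  attr(w, "pair") <- c("odor1", "odor2")
  rep1 <- discrimination_score(w, tab, "odor1")
  expect_equal(rep1$per_cell$D, (1 / 3) * (2 - 4))
  expect_equal(rep1$total, -2 / 3)
  # p = 0: no contribution regardless of weights
  rep2 <- discrimination_score(w, tab, "odor2")
  expect_equal(rep2$total, 0)
})

test_that("a cell reliable for A and silent for B dominates after extended training", {
  # the enumerated class combinations for odor pair (A, B)
  counts <- matrix(c(6, 0,    # reliable A, silent B
                     6, 6,    # reliable A, reliable B
                     6, 2,    # reliable A, unreliable B
                     2, 0,    # unreliable A, silent B
                     2, 2,    # unreliable A, unreliable B
                     0, 6),   # silent A, reliable B
                   6, 2, byrow = TRUE)
  tab <- table_from_counts(counts, n_trials = 6)
  cfg <- training_config(simplified_saturation = TRUE)
  we <- train_association(tab, c(1, 2), cfg, "extended")
  re <- discrimination_score(we, tab)
  expect_equal(which.max(abs(re$per_cell$D)), 1L)
})

test_that("extended training helps unreliable cells on every synthetic pair", {
  cfg <- generator_config("fly", n_cells = 300)
  tcfg <- training_config(simplified_saturation = TRUE)
  for (spec in list(c(0.6, 201), c(0.05, 82))) {
    pair <- generate_correlated_pair(cfg, spec[1], seed = spec[2])
    tab <- classify_cells(detect_significant(pair))
    rn <- discrimination_score(train_association(tab, c(1, 2), tcfg, "normal"),
                               tab)
    re <- discrimination_score(train_association(tab, c(1, 2), tcfg, "extended"),
                               tab)
    ur <- function(r) r$by_class$D_signed[r$by_class$class == "unreliable"]
    rl <- function(r) r$by_class$D_signed[r$by_class$class == "reliable"]
    expect_gt(ur(re), ur(rn))
    expect_lte(rl(re), rl(rn) + 1e-12)
    if (spec[1] > 0.5) {
      # per-class profile of the similar pair: peak at reliability 1,
      # declining trend, no gain at the reliable levels
      contrib <- contribution_by_reliability(rn, re)
      expect_equal(which.max(contrib$improvement), 1L)
      trend <- coef(lm(improvement ~ n_responses, data = contrib))[2]
      expect_lt(trend, 0)
      expect_true(all(contrib$improvement[contrib$n_responses > 3] <= 1e-12))
    }
  }
})

test_that("reliable-cell discrimination drops from dissimilar to similar pairs", {
  cfg <- generator_config("fly", n_cells = 150)
  tcfg <- training_config(simplified_saturation = TRUE)
  score <- function(target, seed, cls) {
    pair <- generate_correlated_pair(cfg, target, seed = seed)
    tab <- classify_cells(detect_significant(pair))
    re <- discrimination_score(train_association(tab, c(1, 2), tcfg,
                                                 "extended"), tab)
    re$by_class$D_signed[re$by_class$class == cls]
  }
  expect_gt(score(0.05, 91, "reliable"), score(0.6, 92, "reliable"))
})
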