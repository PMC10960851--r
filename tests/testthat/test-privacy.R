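# Membership disclosure: attack construction, F1 accounting, invariances.

toy_attack <- function() {
  # two members with distinct quasi-identifiers, two non-members
  attack <- tibble::tibble(
    a = c(1, 0, 1, 0), b = c("u", "u", "w", "w"),
    is_member = c(TRUE, TRUE, FALSE, FALSE)
  )
  synth <- attack[attack$is_member, c("a", "b")]
  cfg <- attack_config(quasi_identifiers = c("a", "b"), member_fraction = 0.5)
  list(attack = attack, synth = synth, cfg = cfg)
}

test_that("an exact-copy synthesizer is maximally disclosive relative to the naive attack", {
  t <- toy_attack()
  res <- membership_attack(t$synth, t$attack, t$cfg)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$f1, 1)
  expect_equal(res$f1_naive, 2 * 0.5 / 1.5)
  expect_equal(res$relative_f1, 1 - 2 / 3, tolerance = 1e-12)
})

test_that("matching everything reproduces the naive attack exactly", {
  t <- toy_attack()
  synth_all <- t$attack[, c("a", "b")]
  res <- membership_attack(synth_all, t$attack, t$cfg)
  expect_equal(res$n_predicted_members, 4)
  expect_equal(res$f1, res$f1_naive)
  expect_equal(res$relative_f1, 0)
})

test_that("an attack with no predicted members scores F1 = 0", {
  t <- toy_attack()
  synth_none <- tibble::tibble(a = c(5, 6), b = c("zz", "qq"))
  res <- membership_attack(synth_none, t$attack, t$cfg)
  expect_equal(res$f1, 0)
  expect_equal(res$relative_f1, -res$f1_naive)
})

test_that("the relative F1 is invariant to row order and to pooling identical copies", {
  pop <- dccg_pop()
  s <- draw_sample(pop, 800, seed = 15)
  m <- fit_sequential(s, schema = pop$schema, control = seq_control("cart"))
  d <- generate(m, 800, seed = 16)
  cfg <- attack_config(setdiff(names(pop$records), "y"),
                       member_fraction = 0.2, attack_sample_size = 300)
  att <- build_attack_sample(pop, attr(s, "row_ids"), cfg, seed = 17)

  base <- membership_attack(d, att, cfg, schema = pop$schema)
  perm <- membership_attack(d[rev(seq_len(nrow(d))), ],
                            att[sample(nrow(att)), ], cfg, schema = pop$schema)
  expect_equal(perm$relative_f1, base$relative_f1)

  pooled <- membership_attack(dplyr::bind_rows(d, d, d), att, cfg,
                              schema = pop$schema)
  expect_equal(pooled$relative_f1, base$relative_f1)
})

test_that("the hamming threshold relaxes matching monotonically", {
  t <- toy_attack()
  # synthetic differs from each member in exactly one quasi-identifier
  synth <- tibble::tibble(a = c(1, 0), b = c("x", "x"))
  cfg0 <- t$cfg
  cfg1 <- attack_config(c("a", "b"), member_fraction = 0.5, hamming_threshold = 1)
  r0 <- membership_attack(synth, t$attack, cfg0)
  r1 <- membership_attack(synth, t$attack, cfg1)
  expect_equal(r0$n_predicted_members, 0)
  expect_gte(r1$n_predicted_members, 2)
})

test_that("attack samples have the configured member mix and are reproducible", {
  pop <- dccg_pop()
  s <- draw_sample(pop, 2625, seed = 19)
  rho <- 2625 / 30000
  cfg <- attack_config(setdiff(names(pop$records), "y"), member_fraction = rho,
                       attack_sample_size = 400)
  att <- build_attack_sample(pop, attr(s, "row_ids"), cfg, seed = 20)
  expect_equal(nrow(att), 400)
  expect_equal(sum(att$is_member), round(rho * 400))
  att2 <- build_attack_sample(pop, attr(s, "row_ids"), cfg, seed = 20)
  expect_identical(as.data.frame(att), as.data.frame(att2))

  all_mem <- attack_config("sex", member_fraction = 1, attack_sample_size = 100)
  att3 <- build_attack_sample(pop, attr(s, "row_ids"), all_mem, seed = 21)
  expect_true(all(att3$is_member))

  tiny <- attack_config("sex", member_fraction = 1e-5, attack_sample_size = 10)
  expect_error(build_attack_sample(pop, attr(s, "row_ids"), tiny, seed = 22),
               class = "synthrep_config_error")
})

test_that("an independence synthesizer carries negligible membership signal", {
  pop <- dccg_pop()
  s <- draw_sample(pop, 2625, seed = 23)
  # scramble each column independently: marginals kept, joint destroyed
  set.seed(24)
  d <- as.data.frame(lapply(s[setdiff(names(s), "y")],
                            function(col) sample(col, length(col), replace = TRUE)))
  cfg <- attack_config(setdiff(names(pop$records), "y"),
                       member_fraction = 2625 / 30000)
  att <- build_attack_sample(pop, attr(s, "row_ids"), cfg, seed = 25)
  res <- membership_attack(d, att, cfg, schema = pop$schema)
  expect_lte(res$relative_f1, 0.05)
})
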