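test_that("epsilon scaling follows the floor formula and its limits", {
  expect_equal(scale_epsilon(5.6, 0.9, 2.0), 2.36)      # printed worked example
  expect_equal(scale_epsilon(5.6, 0.1, 2.0), 5.24)      # hand evaluation
  eps <- c(2.0, 2.3, 3.5, 5.6)
  expect_equal(scale_epsilon(eps, 0), eps)              # identity at alpha = 0
  for (a in seq(0, 1, by = 0.25))
    expect_equal(scale_epsilon(2.0, a), 2.0)            # floor fixed point
  expect_error(scale_epsilon(1.5, 0.5), "increase attraction")
  expect_error(scale_epsilon(5.6, 1.2), "alpha")
  expect_error(scale_epsilon(5.6, -0.1), "alpha")
})

test_that("scaling is monotone in alpha and order-preserving across levels", {
  ladder <- c(5.6, 5.0, 4.5, 4.0, 3.5, 3.1, 2.7, 2.3, 2.0)
  alphas <- seq(0, 1, by = 0.1)
  prev <- scale_epsilon(ladder, 0)
  for (a in alphas[-1]) {
    cur <- scale_epsilon(ladder, a)
    expect_true(all(cur <= prev + 1e-12))               # non-increasing in alpha
    expect_true(all(cur >= 2.0 - 1e-12))                # never below the floor
    if (a < 1) expect_true(all(diff(cur) < 0))          # ranking preserved
    prev <- cur
  }
  expect_equal(scale_epsilon(ladder, 1), rep(2, 9))     # alpha = 1 hits the floor
  # spread contraction is exactly (1 - alpha) * original spread
  for (a in alphas) {
    s <- scale_epsilon(ladder, a)
    expect_equal(max(s) - min(s), (1 - a) * (5.6 - 2.0))
  }
})

test_that("uniform scaling duplicates protein types and touches nothing else", {
  m <- martini_like_matrix()
  prot <- c("P5", "P4", "Qa", "Qd")
  ff <- apply_uniform_scaling(m, prot, 0.9)
  # only duplicated-duplicated pairs differ from the original
  d <- scaling_diff(ff)
  expect_true(all(grepl("_s$", d$i) & grepl("_s$", d$j)))
  # all nine ladder levels present among protein pairs: scaled extremes
  expect_equal(max(ff$audit$eps_scaled), 2.36)
  expect_equal(min(ff$audit$eps_scaled), 2.00)
  # sigma untouched everywhere, including the duplicated block
  for (r in seq_len(nrow(ff$audit)))
    expect_equal(ff$audit$sigma[r],
                 unname(get_pair(m, sub("_s$", "", ff$audit$type_i[r]),
                                 sub("_s$", "", ff$audit$type_j[r]))["sigma"]))
  # cross pairs duplicated-vs-water equal the original values
  expect_equal(get_pair(ff$scaled, "P4_s", "W"), get_pair(m, "P4", "W"))
  # alpha = 1 with a single type: duplicate-duplicate at the floor
  f1 <- apply_uniform_scaling(m, "P4", 1.0)
  expect_equal(unname(get_pair(f1$scaled, "P4_s", "P4_s")["eps"]), 2.0)
  expect_equal(get_pair(f1$scaled, "W", "P4"), get_pair(m, "W", "P4"))
  # alpha = 0 is bookkeeping-only: scaled pairs identical to originals
  f0 <- apply_uniform_scaling(m, prot, 0)
  expect_equal(nrow(scaling_diff(f0)), 0)
  expect_error(apply_uniform_scaling(m, character(), 0.5), "empty")
  expect_error(apply_uniform_scaling(m, "NOPE", 0.5), "unknown")
  # suffix collision is an error, never a silent rename
  clash <- nonbond_table(c("A", "A_s"),
                         data.frame(i = c("A", "A", "A_s"), j = c("A", "A_s", "A_s"),
                                    eps = 3, sigma = 0.47))
  expect_error(apply_uniform_scaling(clash, "A", 0.5), "collide")
})

test_that("water-contact classification counts contacts with a strict tie rule", {
  frames <- rep(list(classification_frame()), 4)
  cls <- classify_water_contacting_residues(frames, cutoff = 0.6, skip = 0)
  expect_equal(cls$resid, 1L)                           # only residue 1
  counts <- attr(cls, "counts")
  expect_equal(counts$n_water, c(12, 4, 0))             # 3,1,0 per frame x 4
  expect_equal(counts$n_lipid, c(0, 4, 12))
  expect_false(counts$water_contacting[2])              # tie -> not classified
  expect_false(counts$water_contacting[3])
  # skip drops leading frames
  cls2 <- classify_water_contacting_residues(frames, skip = 2)
  expect_equal(attr(cls2, "counts")$n_water[1], 6)
  expect_error(classify_water_contacting_residues(frames, skip = 4), "no frames")
  dry <- classification_frame()
  dry$category[dry$category == "water"] <- "ion"
  expect_error(classify_water_contacting_residues(dry, skip = 0), "undefined")
})

test_that("water-contact classification honours the minimum image", {
  fr <- classification_frame()
  # translate so one residue-1 water wraps across x = 0: the pair sits at
  # plain distance ~9.6 nm but minimum-image distance 0.4 nm
  fr$xyz[, 1] <- (fr$xyz[, 1] + 4.9) %% fr$box[1]
  cls <- classify_water_contacting_residues(fr, skip = 0)
  expect_equal(attr(cls, "counts")$n_water[1], 3)
})

test_that("W scaling rescales only the classified residues' bead types", {
  m <- martini_like_matrix()
  res_types <- data.frame(peptide = 1L, resid = 1:3,
                          type = c("P5", "P4", "Qa"))
  cls <- data.frame(peptide = 1L, resid = 1L)           # residue 1 -> P5 only
  ff <- apply_water_scaling(m, cls, res_types, alpha = 0.6)
  d <- scaling_diff(ff)
  expect_equal(nrow(d), 1)                              # one mutual pair differs
  expect_equal(c(d$i, d$j), c("P5_s", "P5_s"))
  expect_equal(d$eps, scale_epsilon(unname(get_pair(m, "P5", "P5")["eps"]), 0.6))
  # scaled-unscaled protein cross stays standard
  expect_equal(get_pair(ff$scaled, "P5_s", "P4"), get_pair(m, "P5", "P4"))
  # alpha = 0.9 on the strongest level reproduces the printed 2.36
  ff9 <- apply_water_scaling(m, cls, res_types, alpha = 0.9)
  expect_equal(unname(get_pair(ff9$scaled, "P5_s", "P5_s")["eps"]), 2.36)
  # zero classified residues: emitted table identical to the original
  ff0 <- apply_water_scaling(m, cls[0, ], res_types, alpha = 0.9)
  expect_true(nonbond_equal(ff0$scaled, m))
})

test_that("sub-floor small-bead pairs are fixed points of the rewriters", {
  m <- martini_like_matrix(include_small = TRUE)
  ff <- apply_uniform_scaling(m, c("SQd", "SQa"), 0.9)  # small twins, eps 1.5-4.2
  a <- ff$audit
  low <- a[a$eps_original < 2, ]
  expect_true(nrow(low) > 0)
  expect_equal(low$eps_scaled, low$eps_original)        # unchanged, not raised
  expect_true(all(a$eps_scaled <= a$eps_original + 1e-12))
})
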