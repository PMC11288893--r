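test_that("the threonine beta-sheet fingerprint classifies as sheet", {
  # Thr Calpha ~61.2 ppm with a high-frequency Cbeta ~72.3 ppm is the
  # beta-sheet signature
  post <- class_posterior("THR", ca = 61.2, cb = 72.3)
  expect_equal(attr(post, "map"), "sheet")
  expect_gt(post[["sheet"]], max(post[["helix"]], post[["coil"]]))
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_equal(classify_cb_band("THR", 72.3)$class, "sheet")
})

test_that("observations at a class mean recover that class", {
  stats <- load_shift_statistics()
  for (cls in c("helix", "sheet", "coil")) {
    row <- stats[stats$residue_type == "THR" & stats$ss_class == cls, ]
    post <- class_posterior("THR", ca = row$mean_ca, cb = row$mean_cb)
    expect_equal(attr(post, "map"), cls)
    zb <- classify_cb_band("THR", row$mean_cb)
    expect_equal(zb$class, cls)
    expect_equal(unname(zb$z_scores[cls]), 0)
  }
  expect_error(class_posterior("XYZ", ca = 60), "no shift statistics")
  expect_error(class_posterior("THR"), "at least one")
})

test_that("identical classes split the posterior evenly", {
  stats <- data.frame(residue_type = "THR",
                      ss_class = c("helix", "sheet"),
                      mean_ca = c(62, 62), sd_ca = c(1, 1),
                      mean_cb = c(70, 70), sd_cb = c(1, 1))
  post <- class_posterior("THR", ca = 63.4, cb = 69.1, stats = stats)
  expect_equal(unname(post[["helix"]]), 0.5, tolerance = 1e-12)
  expect_equal(unname(post[["sheet"]]), 0.5, tolerance = 1e-12)
})

test_that("posteriors are translation equivariant", {
  stats <- load_shift_statistics()
  shifted <- stats
  delta <- 11.7
  shifted$mean_ca <- shifted$mean_ca + delta
  shifted$mean_cb <- shifted$mean_cb + delta
  p0 <- class_posterior("THR", ca = 61.2, cb = 72.3, stats = stats)
  p1 <- class_posterior("THR", ca = 61.2 + delta, cb = 72.3 + delta,
                        stats = shifted)
  expect_equal(as.numeric(p0), as.numeric(p1), tolerance = 1e-12)
})

test_that("Cbeta band assignment agrees with the 1D density argmax", {
  stats <- load_shift_statistics()
  s <- stats[stats$residue_type == "THR", ]
  for (cb in seq(64, 78, by = 0.05)) {
    got <- classify_cb_band("THR", cb, stats)
    dens <- setNames(dnorm(cb, s$mean_cb, s$sd_cb), s$ss_class)
    if (got$tie) next
    # densities share no exact ties on this grid off the crossing points
    if (abs(sort(dens, decreasing = TRUE)[1] -
            sort(dens, decreasing = TRUE)[2]) < 1e-12) next
    expect_equal(got$class, names(which.max(dens)))
  }
})

test_that("sampled observations classify back to their class", {
  obs <- make_shift_observations("THR", n_per_class = 500, seed = 21)
  pred <- vapply(seq_len(nrow(obs)), function(i)
    attr(class_posterior("THR", ca = obs$ca[i], cb = obs$cb[i]), "map"),
    character(1))
  expect_gt(mean(pred == obs$true_class), 0.8)
})

test_that("peak back-prediction has the expected combinatorics", {
  tab <- assignment_table(
    residue_index = rep(1:3, each = 3),
    residue_type = rep(c("ALA", "THR", "SER"), each = 3),
    atom_name = rep(c("N", "CA", "C"), 3),
    shift = c(120, 52, 178, 118, 62, 176, 116, 58, 177))
  nca <- predict_correlation_peaks(tab, "NCA")
  nco <- predict_correlation_peaks(tab, "NCO")
  expect_equal(nrow(nca), 3)   # every residue has N and CA
  expect_equal(nrow(nco), 2)   # the first residue has no preceding C'
  expect_equal(sort(nco$dim2_ppm), sort(c(178, 176)))

  # DARR intra-residue pairs: {CA, CB, CG} -> 3 pairs x 2 symmetric spots
  tab2 <- assignment_table(1, rep("LEU", 3), c("CA", "CB", "CG"),
                           c(55, 42, 27))
  expect_equal(nrow(predict_correlation_peaks(tab2, "DARR")), 6)

  # missing atoms are skipped and counted
  tab3 <- assignment_table(1:2, c("ALA", "ALA"), c("N", "N"), c(120, 121))
  nca3 <- predict_correlation_peaks(tab3, "NCA")
  expect_equal(nrow(nca3), 0)
  expect_equal(attr(nca3, "skipped"), 2)
})

test_that("back-prediction is invariant to assignment row order", {
  set.seed(14)
  tab <- assignment_table(
    residue_index = rep(1:4, each = 4),
    residue_type = rep("THR", 16),
    atom_name = rep(c("N", "CA", "CB", "C"), 4),
    shift = round(runif(16, 20, 180), 2))
  perm <- sample(nrow(tab))
  tab_shuf <- assignment_table(tab$residue_index[perm],
                               tab$residue_type[perm],
                               tab$atom_name[perm], tab$shift[perm])
  for (exp in c("DARR", "NCA", "NCO")) {
    a <- predict_correlation_peaks(tab, exp)
    b <- predict_correlation_peaks(tab_shuf, exp)
    expect_equal(a$label, b$label)
    expect_equal(a$dim1_ppm, b$dim1_ppm)
  }
})
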