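test_that("identical configurations generate bit-identical datasets", {
  cfg <- synthetic_config(leukocyte_classes("binary"), 5, image_size = 40,
                          seed = 123)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, d2$labels)
  d3 <- generate_dataset(synthetic_config(leukocyte_classes("binary"), 5,
                                          image_size = 40, seed = 124))
  expect_false(identical(d1$images, d3$images))
})

test_that("generated datasets are balanced and satisfy the image invariants", {
  cfg <- synthetic_config(leukocyte_classes("six"), 4, image_size = 48,
                          seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds), 24)
  expect_true(all(table(ds$labels) == 4))
  expect_equal(dim(ds$images)[1:3], c(48L, 48L, 3L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_false(anyDuplicated(ds$sample_id) > 0)
})

test_that("too-small image sizes are rejected as configuration errors", {
  expect_error(synthetic_config(leukocyte_classes("binary"), 5,
                                image_size = 16), "configuration error")
  expect_error(render_cell(leukocyte_classes("binary")$blast, 16),
               "configuration error")
})

test_that("zero chromatin amplitude leaves the nucleus flat before global noise", {
  spec <- morphology_class_spec("flat", nucleus_frac = c(0.5, 0),
                                chromatin_amp = 0, color_sd = 0)
  set.seed(4)
  s <- render_cell(spec, 48, global_noise_sd = 0)
  nuc <- attr(s, "nucleus_mask")
  expect_true(sum(nuc) > 0)
  for (ch in 1:3) expect_equal(sd(s$pixels[, , ch][nuc]), 0)
  # and a positive amplitude injects intra-nucleus variance
  spec$chromatin_amp <- 0.1
  set.seed(4)
  s2 <- render_cell(spec, 48, global_noise_sd = 0)
  expect_gt(sd(s2$pixels[, , 1][attr(s2, "nucleus_mask")]), 0)
})

test_that("anucleate cells measure a zero nucleus fraction", {
  spec <- morphology_class_spec("frag", has_nucleus = FALSE,
                                radius_frac = c(0.2, 0.02))
  set.seed(1)
  s <- render_cell(spec, 48)
  m <- measure_morphology(s)
  expect_equal(m$nucleus_area_fraction, 0)
  expect_equal(m$lobe_count, 0L)
})

test_that("a fixed lobe count renders as that many connected components", {
  spec <- morphology_class_spec("seg", nucleus_frac = c(0.3, 0), lobes = 3,
                                radius_frac = c(0.6, 0))
  hits <- vapply(1:10, function(i) {
    set.seed(i)
    s <- render_cell(spec, 65, global_noise_sd = 0)
    measure_morphology(s)$lobe_count
  }, integer(1))
  # non-overlapping placement is geometrically feasible at this area fraction
  expect_true(all(hits == 3L))
})

test_that("measure_morphology matches hand-counted masks and flags empty cells", {
  cell <- matrix(FALSE, 20, 20); cell[1:10, 1:10] <- TRUE       # 100 px
  nuc <- matrix(FALSE, 20, 20)
  nuc[1:5, 1:2] <- TRUE                                          # 10 px lobe
  nuc[7:8, 6:10] <- TRUE                                         # 10 px lobe
  m <- measure_morphology(nucleus_mask = nuc, cell_mask = cell)
  expect_equal(m$nucleus_area_fraction, 0.2)
  expect_equal(m$lobe_count, 2L)
  m1 <- measure_morphology(nucleus_mask = cell, cell_mask = cell)
  expect_equal(m1$nucleus_area_fraction, 1.0)
  expect_error(
    measure_morphology(nucleus_mask = nuc,
                       cell_mask = matrix(FALSE, 20, 20)),
    "undefined")
})

test_that("effect size 0 collapses the class-conditional morphology", {
  cfg <- synthetic_config(leukocyte_classes("binary"), 200, image_size = 40,
                          effect_size = 0, distractors = FALSE, seed = 31)
  ds <- generate_dataset(cfg)
  m <- measure_dataset(ds)
  p <- t.test(nucleus_area_fraction ~ label, data = m)$p.value
  expect_gt(p, 0.01)
})

test_that("full effect size separates blast-like from lymphocyte-like N:C ratios", {
  cfg <- synthetic_config(leukocyte_classes("binary"), 100, image_size = 40,
                          effect_size = 1, seed = 32)
  m <- measure_dataset(generate_dataset(cfg))
  means <- tapply(m$nucleus_area_fraction, m$label, mean)
  expect_gt(means[["blast"]] - means[["nonblast"]], 0.2)
})

test_that("threshold-classifier AUC on the N:C ratio is monotone in effect size", {
  aucs <- vapply(c(0, 0.5, 1), function(e) {
    cfg <- synthetic_config(leukocyte_classes("binary"), 200, image_size = 40,
                            effect_size = e, distractors = FALSE, seed = 77)
    m <- measure_dataset(generate_dataset(cfg))
    roc_auc(m$nucleus_area_fraction, m$label == "blast")
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.02))  # sampling slack
  expect_gt(aucs[3], aucs[1])
})
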