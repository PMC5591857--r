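make_ct <- function(zenk_drug = c(25, 25.4, 24.8), zenk_veh = c(26, 26.2, 25.8),
                    hk = 12) {
  nb <- length(zenk_drug)
  drug <- tibble::tibble(bird = sprintf("d%d", seq_len(nb)), group = "hdac3i",
                         ct_zenk = zenk_drug)
  veh <- tibble::tibble(bird = sprintf("v%d", seq_along(zenk_veh)),
                        group = "vehicle", ct_zenk = zenk_veh)
  dplyr::bind_rows(drug, veh) |>
    tidyr::pivot_longer(ct_zenk, values_to = "ct") |>
    dplyr::transmute(bird, group, hemisphere = "left", region = "NCM",
                     gene = "zenk", ct) |>
    dplyr::bind_rows(
      tibble::tibble(bird = c(drug$bird, veh$bird),
                     group = rep(c("hdac3i", "vehicle"),
                                 c(nrow(drug), nrow(veh))),
                     hemisphere = "left", region = "NCM", gene = "s18", ct = hk)
    )
}

test_that("relative expression matches hand-computed 2^(-ddCT)", {
  ct <- make_ct(zenk_drug = c(25, 25, 25), zenk_veh = c(26, 26, 26))
  rel <- delta_delta_ct(ct)
  # drug is one cycle below vehicle with equal housekeeping: 200%
  expect_equal(rel$rel_expression[rel$group == "hdac3i"], rep(200, 3))
  expect_equal(rel$rel_expression[rel$group == "vehicle"], rep(100, 3))
  expect_equal(rel$ddct[rel$group == "hdac3i"], rep(-1, 3))
})

test_that("reference-group mean is exactly 100% even under noise", {
  set.seed(30)
  ct <- make_ct(zenk_drug = 25 + rnorm(5, 0, 0.4),
                zenk_veh = 26 + rnorm(5, 0, 0.4))
  rel <- delta_delta_ct(ct)
  expect_equal(mean(rel$rel_expression[rel$group == "vehicle"]), 100)
  # classic ct-mean convention: geometric (not arithmetic) mean is 100%
  rel_ct <- delta_delta_ct(ct, reference_aggregate = "ct_mean")
  veh <- rel_ct$rel_expression[rel_ct$group == "vehicle"]
  expect_equal(exp(mean(log(veh))), 100)
  expect_gt(mean(veh), 100)
})

test_that("common CT shifts leave relative expression unchanged", {
  set.seed(31)
  ct <- make_ct(zenk_drug = 25 + rnorm(4, 0, 0.3),
                zenk_veh = 26 + rnorm(4, 0, 0.3))
  shifted <- dplyr::mutate(ct, ct = ct + 3)  # affects target and housekeeping
  expect_equal(delta_delta_ct(shifted)$rel_expression,
               delta_delta_ct(ct)$rel_expression, tolerance = 1e-12)
})

test_that("missing housekeeping or empty reference cells are named errors", {
  ct <- make_ct()
  expect_error(delta_delta_ct(ct[!(ct$bird == "d1" & ct$gene == "s18"), ]),
               "missing housekeeping CT.*d1")
  expect_error(delta_delta_ct(ct[ct$group != "vehicle", ]),
               'reference group "vehicle" is empty')
  expect_error(delta_delta_ct(ct, housekeeping_gene = "gapdh"),
               "housekeeping_gene")
})

test_that("expression contrasts detect a constructed left-NCM fold change", {
  fc <- tibble::tibble(group = "hdac3i", hemisphere = "left", region = "NCM",
                       gene = "zenk", fold = 2)
  ct <- generate_qpcr(fold_changes = fc, noise_sd = 0.15, seed = 5)
  rel <- delta_delta_ct(ct)
  con <- expression_contrast(rel)
  left <- con[con$gene == "zenk" & con$region == "NCM" & con$hemisphere == "left", ]
  right <- con[con$gene == "zenk" & con$region == "NCM" & con$hemisphere == "right", ]
  expect_lt(left$p_adjusted, 0.05)
  expect_gt(right$p_adjusted, 0.05)
  expect_equal(left$df, 8)  # two-sample pooled form, 5 + 5 birds
  expect_gt(left$mean_rel_treatment, 150)
  # one-sample form against the 100% reference level
  con1 <- expression_contrast(rel, method = "one_sample")
  left1 <- con1[con1$gene == "zenk" & con1$region == "NCM" &
                  con1$hemisphere == "left", ]
  expect_equal(left1$df, 4)
  expect_lt(left1$p_adjusted, 0.05)
})

test_that("larger true fold changes give larger mean relative expression", {
  set.seed(32)
  means <- vapply(c(1, 1.5, 2, 3), function(f) {
    fc <- tibble::tibble(group = "hdac3i", hemisphere = "left", region = "NCM",
                         gene = "zenk", fold = f)
    rel <- delta_delta_ct(generate_qpcr(fold_changes = fc, noise_sd = 0.2,
                                        seed = 40))
    mean(rel$rel_expression[rel$group == "hdac3i" & rel$hemisphere == "left" &
                              rel$region == "NCM" & rel$gene == "zenk"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
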