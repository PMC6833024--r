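# VCDR, rim widths, ISNT scoring and the screening AUC machinery.

test_that("vertical diameter is the occupied row extent", {
  m <- matrix(0L, 40, 40)
  m[11:21, 5] <- 1L
  expect_equal(vertical_diameter(m), 11L)
  expect_equal(vertical_diameter(matrix(0L, 4, 4)), 0L)
  s <- matrix(0L, 4, 4); s[2, 3] <- 1L
  expect_equal(vertical_diameter(s), 1L)
})

test_that("compute_vcdr is the ratio of vertical extents", {
  od <- matrix(0L, 40, 40); od[10:20, 10:30] <- 1L  # 11 rows
  oc <- matrix(0L, 40, 40); oc[13:17, 15:25] <- 1L  # 5 rows
  expect_equal(compute_vcdr(od, oc), 5 / 11)
  expect_equal(compute_vcdr(od, od), 1)
  expect_equal(compute_vcdr(od, matrix(0L, 40, 40)), 0)
  expect_error(compute_vcdr(matrix(0L, 4, 4), matrix(0L, 4, 4)), "empty")
})

test_that("rim widths are uniform for concentric circles and asymmetric
           for a shifted cup", {
  sp <- phantom_spec(side = 201L, disc_center = c(101, 101),
                     disc_axes = c(40, 40), cup_frac = c(0.3, 0.3),
                     seed = 1L)
  ph <- generate_phantom(sp)
  w <- rim_widths(ph$od_mask, ph$oc_mask)
  expect_lt(max(w) - min(w), 1)          # equal across sectors within 1 px
  expect_equal(unname(w["I"]), 0.7 * 40, tolerance = 0.05)
  # empty cup: widths approach the disc radius
  w0 <- rim_widths(ph$od_mask, matrix(0L, 201, 201))
  expect_equal(unname(w0["S"]), 40, tolerance = 0.05)
  # cup shifted towards the image top: inferior rim wider than superior
  sp2 <- phantom_spec(side = 201L, disc_center = c(101, 101),
                      disc_axes = c(40, 40), cup_frac = c(0.4, 0.4),
                      cup_offset = c(-10, 0), seed = 1L)
  ph2 <- generate_phantom(sp2)
  w2 <- rim_widths(ph2$od_mask, ph2$oc_mask)
  expect_gt(w2["I"], w2["S"])
  expect_error(rim_widths(matrix(0L, 5, 5), matrix(0L, 5, 5)), "empty")
})

test_that("ISNT score counts strict inequalities and laterality swaps N/T", {
  expect_equal(isnt_score(c(I = 10, S = 8, N = 6, T = 4)), 3)
  expect_equal(isnt_score(c(I = 4, S = 6, N = 8, T = 10)), 0)
  expect_equal(isnt_score(c(I = 5, S = 5, N = 5, T = 5)), 0)
  sp <- phantom_spec(side = 151L, disc_center = c(76, 76),
                     disc_axes = c(30, 30), cup_frac = c(0.4, 0.4),
                     cup_offset = c(0, 8), seed = 2L)
  ph <- generate_phantom(sp)
  wr <- rim_widths(ph$od_mask, ph$oc_mask, eye = "right")
  wl <- rim_widths(ph$od_mask, ph$oc_mask, eye = "left")
  expect_equal(unname(wr["N"]), unname(wl["T"]))
  expect_equal(unname(wr["T"]), unname(wl["N"]))
})

test_that("screening score reduces to VCDR at gamma 0 and adds the ISNT
           deficit otherwise", {
  expect_equal(screening_score(0.55, 1), 0.55)
  expect_equal(screening_score(0.5, 0, gamma = 0.3), 0.8)
  expect_equal(screening_score(0.42, 3, gamma = 0.3), 0.42)
  expect_equal(vcdr_difference(0.6, 0.45), 0.15)
  expect_equal(vcdr_difference(0.45, 0.6), 0.15)
  expect_equal(vcdr_difference(0.5, 0.5), 0)
})

test_that("screening from perfect masks separates the label rule exactly", {
  ds <- generate_dataset(40, rare_fraction = 0.1, side = 96L, seed = 23L)
  scores <- vapply(ds$items, function(it)
    compute_vcdr(it$od_mask, it$oc_mask), numeric(1))
  labels <- vapply(ds$items, `[[`, integer(1), "label")
  expect_gte(sum(labels), 1)
  expect_gte(sum(1 - labels), 1)
  expect_equal(roc_auc(scores, labels), 1)
})

test_that("screening_record assembles consistent fields", {
  sp <- phantom_spec(side = 151L, disc_center = c(76, 76),
                     disc_axes = c(30, 30), cup_frac = c(0.5, 0.5), seed = 5L)
  ph <- generate_phantom(sp)
  rec <- screening_record(ph$od_mask, ph$oc_mask)
  expect_equal(rec$vcdr, rec$vcd / rec$vdd)
  expect_true(rec$isnt_score %in% 0:3)
  expect_equal(rec$screening_score, rec$vcdr)
})
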