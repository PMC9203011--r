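test_that("elliptical ranks reflect position in the principal-axis ellipse", {
  # plus-sign layout: the centre channel sits at the centroid, rank 0
  plus <- build_layout(positions = data.frame(x_nm = 36 * c(0, 1, -1, 0, 0),
                                              y_nm = 36 * c(0, 0, 0, 1, -1)))
  r <- elliptical_ranks(plus)
  expect_equal(r[1], 0)
  expect_true(all(r[-1] > 0))

  # collinear row: zero-variance axis handled with a warning; the middle
  # channel has the strictly smallest rank
  row3 <- build_layout(positions = data.frame(x_nm = c(0, 36, 72), y_nm = 0))
  expect_warning(rr <- elliptical_ranks(row3), "zero-variance")
  expect_lt(rr[2], min(rr[c(1, 3)]))

  # symmetric square: ranks invariant under a 90-degree rotation
  sq <- build_layout(positions = data.frame(x_nm = 36 * c(0, 1, 0, 1),
                                            y_nm = 36 * c(0, 0, 1, 1)))
  rot <- build_layout(positions = data.frame(x_nm = -36 * c(0, 0, 1, 1),
                                             y_nm = 36 * c(0, 1, 0, 1)))
  expect_equal(sort(elliptical_ranks(sq)), sort(elliptical_ranks(rot)))

  # single channel
  one <- build_layout(positions = data.frame(x_nm = 0, y_nm = 0))
  expect_equal(elliptical_ranks(one), 0)
})

test_that("selection counts are exact and inner/outer follow rank order", {
  lay <- build_layout("G1")
  for (k in c(10, 25)) {
    sel <- select_phosphorylated(lay, "inner", k / 50)
    expect_equal(sum(sel$phosphorylated), k)
    r <- elliptical_ranks(lay)
    expect_lte(max(r[sel$phosphorylated]), min(r[!sel$phosphorylated]) + 1e-12)
    out <- select_phosphorylated(lay, "outer", k / 50)
    expect_equal(sum(out$phosphorylated), k)
    expect_gte(min(r[out$phosphorylated]), max(r[!out$phosphorylated]) - 1e-12)
    # mean rank of the inner selection is strictly below its complement
    expect_lt(mean(r[sel$phosphorylated]), mean(r[!sel$phosphorylated]))
  }
  expect_true(all(select_phosphorylated(lay, "blanket", 1)$phosphorylated))
  expect_false(any(select_phosphorylated(lay, "none")$phosphorylated))
  expect_true(all(select_phosphorylated(lay, "inner", 1)$phosphorylated))
})

test_that("inner(k) and outer(n - k) partition a cluster with distinct ranks", {
  # an irregular cluster with no mirror symmetry, hence no rank ties
  set.seed(31)
  g <- expand.grid(x = 0:5, y = 0:5)
  g <- g[sample(nrow(g), 17), ]
  lay <- build_layout(positions = data.frame(x_nm = g$x * 36, y_nm = g$y * 36))
  r <- elliptical_ranks(lay)
  expect_equal(anyDuplicated(r), 0L)
  inner <- select_phosphorylated(lay, "inner", 5 / 17)$phosphorylated
  outer <- select_phosphorylated(lay, "outer", 12 / 17)$phosphorylated
  expect_equal(inner, !outer)
})

test_that("a plus-sign inner selection of one picks the central channel", {
  plus <- build_layout(positions = data.frame(x_nm = 36 * c(0, 1, -1, 0, 0),
                                              y_nm = 36 * c(0, 0, 0, 1, -1)))
  sel <- select_phosphorylated(plus, "inner", 0.2)
  expect_equal(which(sel$phosphorylated), 1L)
})

test_that("uniform selection is reproducible under a seed and inner dominance holds for built-ins", {
  lay <- build_layout("G3")
  set.seed(11); a <- select_phosphorylated(lay, "uniform", 0.5)
  set.seed(11); b <- select_phosphorylated(lay, "uniform", 0.5)
  expect_identical(a$phosphorylated, b$phosphorylated)
  expect_equal(sum(a$phosphorylated), 25)
  for (g in c("G1", "G2", "G3", "G4", "G5")) {
    l <- build_layout(g)
    r <- elliptical_ranks(l)
    for (k in c(10, 25)) {
      inner <- select_phosphorylated(l, "inner", k / 50)$phosphorylated
      expect_lt(mean(r[inner]), mean(r[!inner]),
                label = paste(g, k, "inner mean rank"))
    }
  }
})

test_that("K values follow the sensitivity table", {
  lay <- build_layout("G1")
  none <- make_assignment(lay, "none")
  expect_true(all(none$K_plus == 55))
  set.seed(5)
  uni <- make_assignment(lay, "uniform", 0.5)
  expect_equal(sum(uni$K_plus == 25), 25)
  expect_equal(sum(uni$K_plus == 55), 25)
  expect_true(all(uni$K_plus[uni$phosphorylated] == 25))
  b20 <- make_assignment(lay, "blanket", blanket_vs = 0.2)
  expect_true(all(b20$K_plus == 45))
  b50 <- make_assignment(lay, "blanket", blanket_vs = 0.5)
  expect_true(all(b50$K_plus == 35))
  expect_error(make_assignment(lay, "blanket"), "blanket_vs")
  expect_error(select_phosphorylated(lay, "sideways"))
})

test_that("assignments export to CSV", {
  lay <- desk_layout("compact")
  set.seed(2)
  asg <- make_assignment(lay, "uniform", 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_assignment_csv(asg, lay, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 16)
  expect_equal(sum(df$phosphorylated), 8)
  expect_setequal(unique(df$K_plus_uM), c(25, 55))
})
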