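test_that("pattern table loading validates structure and rejects bad input", {
  tab <- load_pattern_table(pattern_table_path())
  expect_equal(nrow(tab), length(unique(tab$smarts)))
  expect_true(all(c("smarts", "dg_strength_kcal") %in% names(tab)))
  expect_gte(nrow(tab), 4)

  empty <- withr::local_tempfile(lines = "smarts\tdg_strength_kcal",
                                 fileext = ".tsv")
  expect_warning(out <- load_pattern_table(empty), "empty")
  expect_equal(nrow(out), 0)

  dup <- withr::local_tempfile(
    lines = c("smarts\tdg_strength_kcal", "[cH1]cN\t-1", "[cH1]cN\t-2"),
    fileext = ".tsv")
  expect_error(load_pattern_table(dup), class = "regiopd_input_error")

  bad <- withr::local_tempfile(
    lines = c("smarts\tdg_strength_kcal", "[cH1](((\t-1"), fileext = ".tsv")
  expect_error(load_pattern_table(bad), "malformed",
               class = "regiopd_input_error")
})

test_that("the printed worked example is reproduced row for row", {
  tab <- load_pattern_table(pattern_table_path())
  m <- match_patterns(TABLE1_SMILES, tab)
  # sites in ascending atom order get display ids 1..6; the printed table is
  # (id, smarts, n_heavy, z_sum, strength) for every match, rank-ordered
  sites <- sort(unique(m$site_atom))
  expect_equal(length(sites), 6)
  expected <- list(
    list(id = 1, rows = list(
      c("[cH1]cC(N(C)A)=O", 7, 45, -2.7),
      c("[cH1]cC(N([C,c])[C,c])=O", 7, 45, -2.5),
      c("[cH1]cCN(C)C", 6, 37, -14.3))),
    list(id = 2, rows = list(c("[cH1]c-C(=O)c", 5, 32, -1.7))),
    list(id = 3, rows = list(c("[cH1]c-C(=O)c", 5, 32, -1.7))),
    list(id = 4, rows = list(c("[cH1]c-C(=O)c", 5, 32, -1.7))),
    list(id = 5, rows = list(c("[cH1]c-C(=O)c", 5, 32, -1.7))),
    list(id = 6, rows = list(
      c("[cH1]cC(N(C)A)=O", 7, 45, -2.7),
      c("[cH1]cC(N([C,c])[C,c])=O", 7, 45, -2.5),
      c("[cH1]cCN(C)C", 6, 37, -14.3)))
  )
  for (e in expected) {
    at <- m[m$site_atom == sites[e$id], ]
    expect_equal(nrow(at), length(e$rows))
    for (r in seq_along(e$rows)) {
      expect_equal(at$smarts[r], e$rows[[r]][1])
      expect_equal(at$n_heavy[r], as.numeric(e$rows[[r]][2]))
      expect_equal(at$z_sum[r], as.numeric(e$rows[[r]][3]))
      expect_equal(at$dg_strength_kcal[r], as.numeric(e$rows[[r]][4]))
      expect_equal(at$rank_at_site[r], r)
    }
  }
  # the amide-directed sites win the site prediction over the ketone sites
  pred <- predict_site_from_patterns(TABLE1_SMILES, tab)
  expect_equal(pred$predicted_sites, c(sites[1], sites[6]))
})

test_that("no pattern match gives the explicit no-prediction outcome", {
  tab <- load_pattern_table(pattern_table_path())
  m <- match_patterns("c1ccccc1", tab)
  expect_equal(nrow(m), 0)
  pred <- predict_site_from_patterns("c1ccccc1", tab)
  expect_true(pred$no_prediction)
  expect_null(pred$predicted_sites)
})

test_that("three-key sort equals a reference comparator on random tables", {
  # independent oracle: selection of the maximum under explicit
  # lexicographic comparison, repeated
  ref_sort <- function(df) {
    out <- integer(0)
    left <- seq_len(nrow(df))
    gt <- function(i, j) {
      if (df$n_heavy[i] != df$n_heavy[j]) return(df$n_heavy[i] > df$n_heavy[j])
      if (df$z_sum[i] != df$z_sum[j]) return(df$z_sum[i] > df$z_sum[j])
      if (df$strength[i] != df$strength[j])
        return(df$strength[i] < df$strength[j])
      i < j                                  # stability: keep input order
    }
    while (length(left)) {
      best <- left[1]
      for (k in left) if (gt(k, best)) best <- k
      out <- c(out, best)
      left <- setdiff(left, best)
    }
    out
  }
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    df <- data.frame(n_heavy = sample(3:7, n, replace = TRUE),
                     z_sum = sample(20:50, n, replace = TRUE),
                     strength = round(runif(n, -15, 0), 1))
    got <- regiopd:::three_key_order(df$n_heavy, df$z_sum, df$strength)
    expect_equal(got, ref_sort(df))
  }
})

test_that("equal assigned strengths are all reported as predicted sites", {
  tab <- tibble::tibble(smarts = "[cH1]c-C(=O)c", dg_strength_kcal = -1.7)
  pred <- predict_site_from_patterns("O=C(c1ccccc1)c1ccccc1", tab)
  expect_equal(length(pred$predicted_sites), 4)   # all four ortho sites tie
})

test_that("match records are self-consistent with the matched atoms", {
  tab <- load_pattern_table(pattern_table_path())
  m <- match_patterns(TABLE1_SMILES, tab)
  # z_sum >= 6 * n_heavy: every heavy atom is carbon or heavier
  expect_true(all(m$z_sum >= 6 * m$n_heavy))
  expect_true(all(m$n_heavy >= 1))
  # site atoms really are aromatic CH in the parsed substrate
  sub <- parse_substrate(TABLE1_SMILES)
  at <- sub$atoms[match(m$site_atom, sub$atoms$atom), ]
  expect_true(all(at$aromatic & at$n_h == 1))
})
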