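test_that("regular-polygon angles are exact and guarded", {
  expect_equal(ideal_ring_angle(4), 90)
  expect_equal(ideal_ring_angle(5), 108)
  expect_equal(ideal_ring_angle(6), 120)
  expect_equal(ideal_ring_angle(7), 900 / 7)
  expect_error(ideal_ring_angle(2), class = "regiopd_precondition_error")
})

test_that("ortho pair enumeration matches a brute-force shortest-path oracle", {
  expect_equal(nrow(find_ortho_pairs(parse_substrate("c1ccccc1"))), 0)

  sub <- sub_phenylpyridine()
  pairs <- find_ortho_pairs(sub)
  # brute force: all (sp2 CH, donor) pairs at graph distance 2-5
  g <- igraph::graph_from_data_frame(
    data.frame(from = sub$bonds$i, to = sub$bonds$j), directed = FALSE,
    vertices = data.frame(name = sub$atoms$atom))
  expected <- 0L
  for (s in sub$atoms$atom[sub$atoms$sp2_ch]) {
    for (d in sub$atoms$atom[sub$atoms$dg_donor]) {
      len <- igraph::distances(g, as.character(s), as.character(d))[1, 1]
      if (len >= 2 && len <= 5) expected <- expected + 1L
    }
  }
  expect_equal(nrow(pairs), expected)
  expect_true(all(pairs$ring_size == pairs$path_bonds + 2))
  # the classic 5-membered palladacycle pair is present
  n_idx <- sub$atoms$atom[sub$atoms$element == "N"]
  expect_true(any(pairs$dg_atom == n_idx & pairs$path_bonds == 3))

  # both N- and O-directed pairs appear pre-dedup for a pyridinyl ketone
  ket <- parse_substrate("O=C(c1ccccc1)c1ccccn1")
  kp <- find_ortho_pairs(ket)
  expect_true(all(c("N", "O") %in%
                    ket$atoms$element[match(unique(kp$dg_atom),
                                            ket$atoms$atom)]))
})

test_that("angle deviation arithmetic and inclusive 10% boundary", {
  # regular pentagon: all angles exactly ideal
  theta <- seq(0, 2 * pi, length.out = 6)[1:5]
  pent <- cbind(cos(theta), sin(theta))
  expect_equal(regiopd:::ring_internal_angles(pent),
               rep(108, 5), tolerance = 1e-10)
  # 135 vs ideal 120 deviates by 12.5% -> fails; 132 deviates by exactly 10%
  # -> passes (inclusive boundary)
  expect_false(abs(135 - 120) / 120 <= 0.10)
  expect_true(abs(132 - 120) / 120 <= 0.10)
})

test_that("2D ring-angle filter keeps fusable rings, rejects strained ones", {
  sub <- sub_phenylpyridine()
  pairs <- passes_angle_filter(sub, find_ortho_pairs(sub))
  five <- pairs[pairs$ring_size == 5 & pairs$site_atom == 2, ]
  expect_true(five$angle_ok)                 # phenyl ortho, valid fusion
  bay <- pairs[pairs$site_atom == 5, ]       # bay-region 4-ring, strained
  expect_false(bay$angle_ok)
})

test_that("dedup collapses symmetric sites, symmetric DGs and nitro oxygens", {
  # N,N-dimethylbenzamide: the two ortho CH sites are mirror images
  amide <- parse_substrate("CN(C)C(=O)c1ccccc1")
  pairs <- passes_angle_filter(amide, find_ortho_pairs(amide))
  kept <- dedup_pairs(amide, pairs[pairs$angle_ok, ])
  expect_equal(length(unique(kept$site_atom)), 1)

  # nitrobenzene: both nitro oxygens collapse to one pair per site class
  nitro <- parse_substrate("O=[N+]([O-])c1ccccc1")
  np <- find_ortho_pairs(nitro)
  o_idx <- nitro$atoms$atom[nitro$atoms$element == "O"]
  ortho_pairs <- np[np$site_atom == 4 & np$dg_atom %in% o_idx, ]
  expect_equal(nrow(ortho_pairs), 2)         # pre-dedup: both oxygens
  dd <- dedup_pairs(nitro, np)
  expect_equal(sum(dd$site_atom == 4 & dd$dg_atom %in% o_idx), 1)
})

test_that("dedup is idempotent and the identity on duplicate-free input", {
  sub <- sub_phenylpyridine()
  pairs <- find_ortho_pairs(sub)
  once <- dedup_pairs(sub, pairs)
  twice <- dedup_pairs(sub, once)
  expect_equal(twice, once)
  # duplicate-free: one pair only
  single <- pairs[1, ]
  expect_equal(nrow(dedup_pairs(sub, single)), 1)
})

test_that("enumerate/filter/dedup class structure is renumbering-invariant", {
  smi <- "CN(C)C(=O)c1ccccc1"
  signature <- function(s) {
    sub <- parse_substrate(s)
    pairs <- passes_angle_filter(sub, find_ortho_pairs(sub))
    kept <- dedup_pairs(sub, pairs[pairs$angle_ok, ])
    # renumbering-stable signature: sorted (ring size, site class size)
    cls <- site_symmetry_classes(sub)
    sizes <- as.vector(table(cls$class_id))[
      cls$class_id[match(kept$site_atom, cls$atom)]]
    paste(sort(paste(kept$ring_size, sizes)), collapse = ";")
  }
  ref <- signature(smi)
  ren <- renumber_smiles(smi, n = 10, seed = 7)
  for (s in ren$smiles) expect_equal(signature(s), ref)
})

test_that("retained pairs always satisfy the path and ring-size bounds", {
  for (smi in c("c1ccc(-c2ccccn2)cc1", "CN(C)C(=O)c1ccccc1",
                "CC(=O)Nc1ccccc1", TABLE1_SMILES)) {
    sub <- parse_substrate(smi)
    pairs <- passes_angle_filter(sub, find_ortho_pairs(sub))
    kept <- dedup_pairs(sub, pairs[pairs$angle_ok, ])
    expect_true(all(kept$path_bonds >= 2 & kept$path_bonds <= 5))
    expect_true(all(kept$ring_size %in% 4:7))
  }
})
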