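test_that("PAM typing follows positions 2-3 only", {
  ctx <- paste0(strrep("A", 20), "TGGTTCAG")
  pf <- pam_features(ctx, 20L)
  expect_equal(pf$pam_type, "NGG")
  expect_equal(pf$pam_n, "T")
  expect_equal(pf$downstream_nt_1, "T")
  expect_equal(pf$downstream_nt_2, "T")
  expect_equal(pf$downstream_nt_5, "G")

  expect_equal(pam_features(paste0(strrep("A", 5), "AAG"), 5L)$pam_type,
               "NAG")
  expect_equal(pam_features(paste0(strrep("A", 5), "TTA"), 5L)$pam_type,
               "OTHER")
  expect_error(pam_features("ACGT", 3L), "too short")

  # downstream bases past the context end are flagged missing, not imputed
  short <- pam_features(paste0(strrep("A", 5), "TGGC"), 5L)
  expect_equal(short$downstream_nt_1, "C")
  expect_true(is.na(short$downstream_nt_2))
  expect_true(is.na(short$downstream_nt_5))
})

test_that("GC content handles N exclusion and degenerate input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("GCNNAT"), 0.5)
  expect_error(gc_content("NNN"), "all N")
  set.seed(30)
  for (rep in 1:20) {
    s <- random_seq(sample(10:200, 1))
    g <- gc_content(s)
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
})

test_that("nearest-neighbor enthalpy is a dinucleotide-stack sum", {
  tab <- nn_enthalpy_table()
  expect_length(tab, 16L)
  expect_equal(unname(nn_enthalpy("AA")), unname(tab[["AA"]]))
  expect_equal(unname(tab[["AA"]]), -7.9)   # the AA/TT unified stack
  expect_warning(v <- nn_enthalpy("A"), "shorter")
  expect_equal(v, 0)

  # additivity over every trinucleotide: dH(xyz) = dH(xy) + dH(yz)
  bases <- c("A", "C", "G", "T")
  for (x in bases) for (y in bases) for (z in bases) {
    expect_equal(nn_enthalpy(paste0(x, y, z)),
                 nn_enthalpy(paste0(x, y)) + nn_enthalpy(paste0(y, z)),
                 label = paste0("additivity ", x, y, z))
  }

  # strand symmetry of the duplex table: dH(s) = dH(revcomp(s))
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  set.seed(31)
  for (rep in 1:10) {
    s <- random_seq(12)
    expect_equal(nn_enthalpy(s), nn_enthalpy(revcomp(s)))
  }
  expect_warning(nn_enthalpy("AANTT"), "skipped")
})

test_that("positional nucleotide features index from the PAM-distal end", {
  pn <- positional_nucleotides("ACGTACGTACGTACGTACGT")
  expect_equal(pn$nt_position_2, "C")
  expect_equal(pn$nt_position_4, "T")
  expect_equal(pn$nt_positions_4_5, "TA")
  expect_equal(pn$nt_position_20, "T")

  # 17-nt guide: "position 20" falls back to the PAM-proximal base
  pn17 <- positional_nucleotides("ACGTACGTACGTACGTA")
  expect_equal(pn17$nt_position_20, "A")
  expect_error(positional_nucleotides("ACG"), "at least 5")
})

test_that("feature vectors are registry-ordered, complete and pure", {
  ds <- tiny_dataset()
  f <- featurize_dataset(ds)
  expect_equal(names(f), c("site_id", "label", feature_registry_columns()))
  expect_false(anyNA(f))

  # determinism: identical inputs give identical vectors
  f2 <- featurize_dataset(ds)
  expect_equal(f, f2)

  # on-target rows have an all-clear alignment block and an NGG PAM
  on <- f[f$label == 1L, ]
  expect_true(all(on$mismatches == 0))
  expect_true(all(on$rna_bulges == 0 & on$dna_bulges == 0))
  expect_true(all(on$pam_type.NGG == 1))

  # one-hot groups sum to exactly 1 on generated data
  reg <- feature_registry()
  big <- featurize_dataset(generate_dataset(seed = 6L))
  for (i in which(reg$encoding %in% c("onehot", "onehot_missing"))) {
    cols <- paste0(reg$feature[i], ".", reg$levels[[i]])
    sums <- rowSums(big[, cols])
    if (reg$encoding[i] == "onehot_missing") {
      sums <- sums + big[[paste0(reg$feature[i], ".missing")]]
    }
    expect_true(all(sums == 1), label = paste("one-hot", reg$feature[i]))
  }

  # guide/site linkage mismatch is refused
  expect_error(
    build_feature_vector(ds$guides[1, ], ds$sites[3, ]),
    "linkage mismatch")
})

test_that("the registry manifest is stable and 30 features wide", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 30L)
  expect_equal(sort(unique(reg$block)), c("alignment", "content", "pam"))
  expect_equal(sum(reg$block == "alignment"), 9L)
  # expanded width is fixed and matches the manifest arithmetic
  widths <- ifelse(reg$encoding == "identity", 1L,
                   lengths(reg$levels) +
                     (reg$encoding == "onehot_missing"))
  expect_equal(length(feature_registry_columns()), sum(widths))
})

test_that("file-backed annotation provider overrides neutral defaults", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site_id = "s1", dhs_signal = 2.5,
                                  coding_region = 1), path)
  prov <- annotation_provider_table(path)
  f <- featurize_dataset(ds, annotations = prov)
  expect_equal(f$dhs_signal[f$site_id == "s1"], 2.5)
  expect_equal(f$coding_region[f$site_id == "s1"], 1)
  expect_equal(f$dhs_signal[f$site_id == "s2"], 0)

  readr::write_tsv(tibble::tibble(site_id = "s1", bogus = 1), path)
  expect_error(annotation_provider_table(path), "unknown annotation")
})
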