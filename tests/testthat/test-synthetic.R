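test_that("the default profile reproduces the curated corpus composition", {
  prof <- default_profile()
  expect_equal(nrow(prof$crops), 15L)
  expect_equal(sum(prof$crops$n_guides), 51L)
  expect_equal(sum(prof$crops$n_on), 174L)
  expect_equal(sum(prof$crops$n_off), 205L)
  rice <- prof$crops[prof$crops$crop == "Rice", ]
  expect_equal(rice$n_guides, 8L)
  expect_equal(rice$n_on, 40L)
  expect_equal(rice$n_off, 36L)
})

test_that("profile knobs are validated", {
  expect_error(default_profile(context_length = 10), ">= 23")
  expect_error(default_profile(mismatch_probs = c(0.5, 0.6)),
               "probability mass")
  expect_error(default_profile(pam_proximal_bias = 0.5), ">= 1")
  expect_error(default_profile(bulge_probability = 1.5), "\\[0, 1\\]")
})

test_that("generated guides are uniform ACGT of the requested length", {
  set.seed(40)
  g <- generate_guide("g", 20)
  expect_equal(nchar(g$sequence), 20L)
  expect_match(g$sequence, "^[ACGT]+$")
  expect_error(generate_guide("g", 16), "between 17 and 20")
  expect_error(generate_guide("g", 25), "between 17 and 20")

  # base frequencies approach 1/4 over many draws
  set.seed(41)
  draws <- replicate(500, generate_guide("g", 20)$sequence)
  freq <- table(strsplit(paste(draws, collapse = ""), "")[[1]])
  expect_true(all(abs(freq / sum(freq) - 0.25) < 0.02))
})

test_that("on-targets are exact embeds with canonical PAM", {
  set.seed(42)
  prof <- default_profile()
  for (rep in 1:10) {
    g <- generate_guide("g", sample(17:20, 1))
    s <- embed_on_target(g, "s", prof)
    expect_equal(s$protospacer, g$sequence)
    expect_equal(substr(s$pam, 2, 3), "GG")
    expect_equal(nchar(s$context), prof$context_length)
    expect_equal(s$label, 1L)
    aln <- align_guide_to_site(g$sequence, s$protospacer)
    expect_equal(aln$counts$mismatches, 0L)
    expect_equal(aln$counts$rna_bulges + aln$counts$dna_bulges, 0L)
  }
})

test_that("off-targets always differ from their guide", {
  set.seed(43)
  prof <- default_profile()
  for (rep in 1:50) {
    g <- generate_guide("g", 20)
    s <- mutate_off_target(g, "s", prof)
    expect_equal(s$label, 0L)
    aln <- align_guide_to_site(g$sequence, s$protospacer)
    expect_gte(aln$counts$mismatches + aln$counts$rna_bulges +
                 aln$counts$dna_bulges, 1L)
    expect_true(substr(s$pam, 2, 3) %in% c("GG", "AG"))
  }
  # a concentrated mismatch distribution is honoured when no bulge drawn
  prof3 <- default_profile(mismatch_probs = c(0, 0, 1, 0, 0, 0),
                           bulge_probability = 0)
  for (rep in 1:10) {
    g <- generate_guide("g", 20)
    s <- mutate_off_target(g, "s", prof3)
    aln <- align_guide_to_site(g$sequence, s$protospacer)
    expect_equal(aln$counts$mismatches, 3L)
  }
})

test_that("the PAM-proximal bias suppresses seed-region mismatches", {
  set.seed(44)
  prof <- default_profile(mismatch_probs = c(1, 0, 0, 0, 0, 0),
                          bulge_probability = 0, pam_proximal_bias = 4)
  g <- generate_guide("g", 20)
  pos <- integer(0)
  for (rep in 1:4000) {
    s <- mutate_off_target(g, "s", prof)
    d <- which(strsplit(s$protospacer, "")[[1]] !=
                 strsplit(g$sequence, "")[[1]])
    pos <- c(pos, d)
  }
  rate_seed <- mean(pos %in% 17:20) / 4
  rate_distal <- mean(pos %in% 1:4) / 4
  # per-position rate in the seed should be ~1/4 of the distal rate
  expect_lt(abs(rate_seed / rate_distal - 0.25), 0.25 * 0.2)
})

test_that("dataset generation matches the profile exactly and is seeded", {
  ds <- generate_dataset(seed = 7L)
  expect_equal(class_counts(ds),
               tibble::tibble(n_sites = 379L, n_on = 174L, n_off = 205L))
  prof <- default_profile()
  per_crop <- dplyr::count(
    dplyr::left_join(ds$sites,
                     dplyr::select(ds$guides, guide_id, crop),
                     by = "guide_id"),
    crop, label)
  for (i in seq_len(nrow(prof$crops))) {
    cr <- prof$crops[i, ]
    expect_equal(per_crop$n[per_crop$crop == cr$crop &
                              per_crop$label == 1L], cr$n_on)
    expect_equal(per_crop$n[per_crop$crop == cr$crop &
                              per_crop$label == 0L], cr$n_off)
  }
  # byte-identical regeneration under the same seed
  ds2 <- generate_dataset(seed = 7L)
  expect_identical(ds$sites, ds2$sites)
  expect_identical(ds$guides, ds2$guides)
  ds3 <- generate_dataset(seed = 8L)
  expect_false(identical(ds$sites$context, ds3$sites$context))
})

test_that("labels are consistent with alignment structure by construction", {
  ds <- generate_dataset(seed = 9L)
  gmap <- setNames(ds$guides$sequence, ds$guides$guide_id)
  for (i in seq_len(nrow(ds$sites))) {
    s <- ds$sites[i, ]
    aln <- align_guide_to_site(gmap[[s$guide_id]], s$protospacer)
    dev <- aln$counts$mismatches + aln$counts$rna_bulges +
      aln$counts$dna_bulges
    if (s$label == 1L) {
      expect_equal(dev, 0L, label = s$site_id)
    } else {
      expect_gte(dev, 1L)
    }
  }
})
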