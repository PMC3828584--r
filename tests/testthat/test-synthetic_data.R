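# The synthetic quad-exome generator: validity, determinism, Mendelian
# transmission, planted-signal construction, missingness behaviour.

test_that("generated gene models satisfy every CDS invariant", {
  gm <- generate_gene_models(sim_config(seed = 1, n_genes = 200))
  expect_length(gm$models, 200)
  for (m in gm$models) {
    expect_equal(nchar(m$cds_seq) %% 3, 0)
    expect_equal(substr(m$cds_seq, 1, 3), "ATG")
    aa <- strsplit(model_protein(m), "")[[1]]
    expect_false(any(aa == "*"))               # no internal stop
    expect_true(all(diff(m$exons$start) > 0))
    if (nrow(m$exons) > 1) {
      expect_true(all(m$exons$start[-1] > m$exons$end[-nrow(m$exons)]))
    }
    expect_equal(length(m$cds_map), nchar(m$cds_seq))
    # the genome spells the CDS back out through the map
    chrom <- gm$genome[[m$chrom]]
    bases <- substring(chrom, m$cds_map, m$cds_map)
    if (m$strand == "-") bases <- comp_base(bases)
    expect_equal(paste(bases, collapse = ""), m$cds_seq)
  }
})

test_that("identical configs produce byte-identical datasets", {
  cfg <- sim_config(seed = 5, n_genes = 30, n_background_variants = 300)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(cfg, d1)
  write_dataset(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("intronless genes carry no splice-region positions and refuse intronic plants", {
  cfg <- sim_config(seed = 8, n_genes = 10, exons_per_gene = c(1L, 1L),
                    n_background_variants = 200)
  gm <- generate_gene_models(cfg)
  expect_true(all(vapply(gm$models, function(m) nrow(m$exons), 0L) == 1))
  expect_error(plant_causal(cfg, gm$models, gm$genome), "no intron")
  # homozygous mode needs no intron
  cfg_hom <- sim_config(seed = 8, n_genes = 10, exons_per_gene = c(1L, 1L),
                        planted_mode = "homozygous")
  gm <- generate_gene_models(cfg_hom)
  planted <- plant_causal(cfg_hom, gm$models, gm$genome)
  expect_true(homozygous_qualifies(planted$records[1, ], sim_pedigree()))
})

test_that("background genotypes are Mendelian-consistent; decoys are labelled", {
  sim <- simulate_quad(sim_config(seed = 9))
  bg <- sim$variants[variant_key(sim$variants) %in%
                       sim$truth$background_keys, ]
  expect_gt(nrow(bg), 100)
  for (i in seq_len(nrow(bg))) {
    expect_true(mendel_ok(bg$gt_I1[i], bg$gt_I2[i], bg$gt_II1[i]))
    expect_true(mendel_ok(bg$gt_I1[i], bg$gt_I2[i], bg$gt_II2[i]))
  }
  expect_setequal(unique(sim$truth$decoys$reason),
                  c("cis_only", "single_carrier_hom", "in_databases"))
  expect_equal(nrow(sim$truth$decoys), 6)
})

test_that("the planted compound-het pair passes each filter stage by construction", {
  sim <- simulate_quad(sim_config(seed = 10))
  causal <- sim$truth$causal_variants
  keys <- paste(causal$chrom, causal$pos, causal$ref, causal$alt, sep = ":")
  ann <- annotate_variants(sim$variants, sim$models)
  kept <- functional_filter(ann)
  expect_true(all(keys %in% variant_key(kept)))
  novel <- exclude_known(kept, sim$site_dbs)
  expect_true(all(keys %in% variant_key(novel)))
  cand <- compound_het_qualifies(
    novel[novel$gene == sim$truth$causal_gene, ], sim$pedigree)
  expect_s3_class(cand, "candidate_gene")
  got <- cand$variants[match(keys, variant_key(cand$variants)), ]
  expect_equal(got$origin, causal$origin)
  # the planted intronic variant sits at donor offset +3
  intr <- ann[variant_key(ann) == keys[causal$type == "intronic"], ]
  expect_equal(intr$intron_offset, 3L)
  expect_equal(intr$category, "splice_region")
})

test_that("total missingness erases the candidate (fails closed) and masks are nested", {
  sim <- simulate_quad(sim_config(seed = 11, missingness_rate = 1))
  expect_true(all(is.na(gt_matrix(sim$variants))))
  expect_length(recessive_scan(assign_genes(sim$variants, sim$models),
                               sim$pedigree), 0)
  # nestedness of the mask: every genotype missing at a low rate is missing
  # at any higher rate
  sim0 <- simulate_quad(sim_config(seed = 12))
  v3 <- apply_missingness(sim0$variants, sim0$missing_u, 0.3)
  v6 <- apply_missingness(sim0$variants, sim0$missing_u, 0.6)
  expect_true(all(which(is.na(gt_matrix(v3))) %in%
                    which(is.na(gt_matrix(v6)))))
})

test_that("full database membership removes all background at the exclusion stage", {
  sim <- simulate_quad(sim_config(seed = 13, db_membership_rate = 1,
                                  n_background_variants = 400, n_genes = 50))
  left <- exclude_known(sim$variants, sim$site_dbs)
  # survivors are exactly the planted pair plus the non-catalogued decoys
  expect_false(any(variant_key(left) %in% sim$truth$background_keys))
  causal_keys <- paste(sim$truth$causal_variants$chrom,
                       sim$truth$causal_variants$pos,
                       sim$truth$causal_variants$ref,
                       sim$truth$causal_variants$alt, sep = ":")
  expect_true(all(causal_keys %in% variant_key(left)))
})
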