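# Recessive segregation: shared-homozygous rule, parental origin, in-trans
# compound heterozygosity, and equivalence of the scan with the exhaustive
# oracle. Genotype vectors are (father, mother, child1, child2).

test_that("shared-homozygous rule: children hom-alt, both parents het, fails closed on missing", {
  q <- function(g) quad_variants(1L, list(g))
  expect_true(homozygous_qualifies(q(c(1, 1, 2, 2)), QUAD))
  expect_false(homozygous_qualifies(q(c(1, 1, 2, 1)), QUAD))  # child het
  expect_false(homozygous_qualifies(q(c(2, 1, 2, 2)), QUAD))  # hom parent
  expect_false(homozygous_qualifies(q(c(0, 1, 2, 2)), QUAD))  # non-carrier dad
  expect_false(homozygous_qualifies(q(c(1, NA, 2, 2)), QUAD)) # fails closed
})

test_that("parental origin follows the carrier split", {
  q <- function(g) quad_variants(1L, list(g))
  expect_equal(assign_parental_origin(q(c(0, 1, 1, 1)), QUAD), "mother")
  expect_equal(assign_parental_origin(q(c(1, 0, 1, 1)), QUAD), "father")
  expect_equal(assign_parental_origin(q(c(1, 1, 1, 1)), QUAD), "ambiguous")
  expect_equal(assign_parental_origin(q(c(0, 0, 1, 1)), QUAD), "inconsistent")
  expect_equal(assign_parental_origin(q(c(NA, 1, 1, 1)), QUAD), "ambiguous")
})

test_that("compound het requires at least one maternal and one paternal variant in trans", {
  trans <- quad_variants(c(10L, 20L),
                         list(c(0, 1, 1, 1), c(1, 0, 1, 1)), gene = "G1")
  cand <- compound_het_qualifies(trans, QUAD)
  expect_s3_class(cand, "candidate_gene")
  expect_equal(nrow(cand$variants), 2)
  expect_setequal(cand$variants$origin, c("mother", "father"))

  cis <- quad_variants(c(10L, 20L),
                       list(c(0, 1, 1, 1), c(0, 1, 1, 1)), gene = "G1")
  expect_null(compound_het_qualifies(cis, QUAD))

  # three variants: 2 maternal + 1 paternal all reported
  three <- quad_variants(c(10L, 20L, 30L),
                         list(c(0, 1, 1, 1), c(1, 0, 1, 1), c(0, 1, 1, 1)),
                         gene = "G1")
  expect_equal(nrow(compound_het_qualifies(three, QUAD)$variants), 3)

  # ambiguous-origin variants are listed as unphased extras but do not
  # satisfy the trans requirement on their own
  ambig_only <- quad_variants(c(10L, 20L),
                              list(c(1, 1, 1, 1), c(1, 1, 1, 1)), gene = "G1")
  expect_null(compound_het_qualifies(ambig_only, QUAD))
  with_extra <- quad_variants(c(10L, 20L, 30L),
                              list(c(0, 1, 1, 1), c(1, 0, 1, 1),
                                   c(1, 1, 1, 1)), gene = "G1")
  cand <- compound_het_qualifies(with_extra, QUAD)
  expect_equal(sort(cand$variants$origin),
               c("ambiguous", "father", "mother"))

  # a hom-alt unaffected parent contradicts full penetrance: excluded
  hom_parent <- quad_variants(c(10L, 20L),
                              list(c(0, 2, 1, 1), c(1, 0, 1, 1)), gene = "G1")
  expect_null(compound_het_qualifies(hom_parent, QUAD))
  # a missing genotype fails closed
  miss <- quad_variants(c(10L, 20L),
                        list(c(0, 1, 1, NA), c(1, 0, 1, 1)), gene = "G1")
  expect_null(compound_het_qualifies(miss, QUAD))
})

test_that("recessive_scan equals the exhaustive oracle on every single-variant quad configuration", {
  states <- c(0L, 1L, 2L, NA)
  grid <- expand.grid(f = states, m = states, k1 = states, k2 = states)
  vt <- quad_variants(seq_len(nrow(grid)),
                      lapply(seq_len(nrow(grid)), function(i) {
                        unlist(grid[i, ])
                      }),
                      gene = paste0("G", seq_len(nrow(grid))))
  expect_equal(cand_summary(recessive_scan(vt, QUAD)),
               cand_summary(oracle_recessive(vt, QUAD)))
  # and the qualifying set is exactly the definitional one
  hom_genes <- vapply(recessive_scan(vt, QUAD), `[[`, "", "gene_symbol")
  want <- paste0("G", which(!is.na(grid$f) & !is.na(grid$m) &
                              !is.na(grid$k1) & !is.na(grid$k2) &
                              grid$f == 1 & grid$m == 1 &
                              grid$k1 == 2 & grid$k2 == 2))
  expect_setequal(hom_genes, want)
})

test_that("recessive_scan equals the exhaustive oracle on random multi-variant instances", {
  set.seed(41)
  states <- c(0L, 1L, 2L, NA)
  for (rep in 1:100) {
    n_genes <- sample(1:5, 1)
    rows <- list(); genes <- character(0); pos <- integer(0)
    for (g in seq_len(n_genes)) {
      n_var <- sample(1:4, 1)
      for (v in seq_len(n_var)) {
        rows[[length(rows) + 1L]] <- sample(states, 4, replace = TRUE)
        genes <- c(genes, paste0("G", g))
        pos <- c(pos, length(pos) * 10L + g)
      }
    }
    vt <- quad_variants(pos, rows, gene = genes)
    expect_equal(cand_summary(recessive_scan(vt, QUAD)),
                 cand_summary(oracle_recessive(vt, QUAD)),
                 info = paste("instance", rep))
  }
})

test_that("scan is monotone: more records never lose candidate genes", {
  set.seed(43)
  states <- c(0L, 1L, 2L, NA)
  for (rep in 1:25) {
    rows <- replicate(12, sample(states, 4, replace = TRUE), simplify = FALSE)
    genes <- sample(paste0("G", 1:3), 12, replace = TRUE)
    vt <- quad_variants(seq_len(12) * 7L, rows, gene = genes)
    sub <- vt[sample(nrow(vt), 6), ]
    g_all <- vapply(recessive_scan(vt, QUAD), `[[`, "", "gene_symbol")
    g_sub <- vapply(recessive_scan(sub, QUAD), `[[`, "", "gene_symbol")
    expect_true(all(g_sub %in% g_all))
  }
})

test_that("an added affected child keeps or removes the candidate according to consistency", {
  trans <- quad_variants(c(10L, 20L),
                         list(c(0, 1, 1, 1), c(1, 0, 1, 1)), gene = "G1")
  five <- pedigree("I1", "I2", c("II1", "II2", "II3"))
  consistent <- trans; consistent$gt_II3 <- c(1L, 1L)
  inconsistent <- trans; inconsistent$gt_II3 <- c(0L, 0L)
  expect_length(recessive_scan(consistent, five), 1)
  expect_length(recessive_scan(inconsistent, five), 0)
})

test_that("gene-list intersection narrows candidates by symbol", {
  cands <- lapply(sprintf("G%02d", 1:83), function(g) {
    candidate_gene(g, "homozygous",
                   quad_variants(1L, list(c(1, 1, 2, 2)), gene = g))
  })
  keep <- intersect_known_genes(cands, structure("G42", class = "gene_list"))
  expect_length(keep, 1)
  expect_equal(keep[[1]]$gene_symbol, "G42")
  expect_length(intersect_known_genes(cands, character(0)), 0)
  all_list <- structure(sprintf("g%02d", 1:83), class = "gene_list")
  expect_length(intersect_known_genes(cands, all_list), 83)  # case-blind
})

test_that("dual-mode genes are reported once, as homozygous, flagged", {
  both <- quad_variants(c(10L, 20L, 30L),
                        list(c(1, 1, 2, 2),          # shared homozygous
                             c(0, 1, 1, 1), c(1, 0, 1, 1)),  # trans pair
                        gene = "G1")
  cands <- recessive_scan(both, QUAD)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$mode, "homozygous")
  expect_true(cands[[1]]$dual_mode)
  expect_equal(cand_summary(cands), cand_summary(oracle_recessive(both, QUAD)))
})
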