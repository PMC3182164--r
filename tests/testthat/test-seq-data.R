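test_that("codon alignments read from FASTA and PHYLIP round-trip exactly", {
  tr <- bal8_tree()
  sim <- simulate_codon_alignment(tr, 2, data.frame(omega = 0.3, weight = 1),
                                  20, code = mito_code, seed = 4)
  for (fmt in c("fasta", "phylip")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_codon_alignment(sim$aln, f, fmt)
    back <- read_codon_alignment(f, fmt)
    expect_identical(unclass(back)[, ], unclass(sim$aln)[, ])
    expect_identical(taxa_labels(back), taxa_labels(sim$aln))
  }
})

test_that("frame and stop-codon violations are rejected with taxon named", {
  # 60 nt, 8 sequences -> 20 codon sites
  seqs <- setNames(rep(paste(rep("ATG", 20), collapse = ""), 8),
                   paste0("tx", 1:8))
  expect_equal(ncol(aln_from_seqs(seqs)), 20)

  # AGA is a stop under the vertebrate mitochondrial code
  bad <- seqs
  substr(bad["tx3"], 16, 18) <- "AGA"
  expect_error(aln_from_seqs(bad), "stop codon 'AGA'.*tx3.*site 6")

  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGATGA", ">b", "ATGATGA"), f)  # length 7
  expect_error(read_codon_alignment(f), "multiple of 3")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_codon_alignment(empty), "parse")
})

test_that("ambiguity codes and gaps become missing codons", {
  a <- aln_from_seqs(c(s1 = "ATGNTTCTA", s2 = "ATG---CTA"))
  expect_true(is.na(unclass(a)[1, 2]))
  expect_true(is.na(unclass(a)[2, 2]))
  expect_identical(unname(unclass(a)[1, 1]), "ATG")
})

test_that("gene concatenation tiles coordinates and checks taxon sets", {
  mk <- function(n) {
    aln_from_seqs(setNames(rep(paste(rep("CTA", n), collapse = ""), 3),
                           c("a", "b", "c")))
  }
  cc <- concatenate_genes(list(g1 = mk(10), g2 = mk(15)))
  gm <- attr(cc, "gene_map")
  expect_equal(ncol(cc), 25)
  expect_equal(gm$start, c(1L, 11L))
  expect_equal(gm$end, c(10L, 25L))

  single <- concatenate_genes(list(g1 = mk(7)))
  expect_equal(ncol(single), 7)

  # 12 genes with distinct names tile 1..S
  parts <- setNames(lapply(3 + seq_len(12), mk), paste0("gene", 1:12))
  cc12 <- concatenate_genes(parts)
  gm12 <- attr(cc12, "gene_map")
  expect_equal(nrow(gm12), 12)
  expect_equal(gm12$start, c(1L, head(cumsum(gm12$end - gm12$start + 1), -1) + 1L))
  expect_equal(gm12$end[12], ncol(cc12))

  bad <- mk(5)
  rownames(bad) <- c("a", "b", "z")
  expect_error(concatenate_genes(list(g1 = mk(5), g2 = bad)), "z")
})

test_that("concatenation is associative and commutes with translation", {
  tr <- tree5()
  mk <- function(seed) {
    simulate_codon_alignment(tr, 2, data.frame(omega = 0.5, weight = 1),
                             8, code = mito_code, seed = seed)$aln
  }
  x <- mk(1); y <- mk(2); z <- mk(3)
  left <- concatenate_genes(list(
    a = concatenate_genes(list(a = x, b = y)), c = z))
  right <- concatenate_genes(list(a = x,
    b = concatenate_genes(list(b = y, c = z))))
  expect_identical(unclass(left)[, ], unclass(right)[, ])

  both <- concatenate_genes(list(a = x, b = y))
  t1 <- translate_codons(both)
  t2 <- cbind(unclass(translate_codons(x)), unclass(translate_codons(y)))
  expect_identical(unclass(t1)[, ], t2[, ])
})

test_that("translation follows the vertebrate mitochondrial code", {
  a <- aln_from_seqs(c(s1 = "ATGTGAATA", s2 = "---TGAATA"))
  aa <- translate_codons(a)
  expect_identical(unname(unclass(aa)[1, ]), c("M", "W", "M"))  # TGA -> W
  expect_identical(unname(unclass(aa)[2, 1]), "-")       # gap propagates
})

test_that("newick trees are validated, unrooted, and resolved", {
  t4 <- read_phylo_tree("((A,B),(C,D));")
  expect_equal(nrow(t4$edge), 5)  # unrooted 4-taxon tree has 5 edges
  expect_false(ape::is.rooted(t4))

  # rooted 8-taxon newick -> 2n-3 = 13 edges after unrooting
  nwk8 <- paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
                 "(((t5:1,t6:1):1,t7:1):1,t8:1):1);")
  t8 <- read_phylo_tree(nwk8)
  expect_equal(nrow(t8$edge), 13)

  expect_error(read_phylo_tree("((A,B),(C,D));", taxa = c("A", "B", "C")),
               "not in alignment: D")
  expect_warning(read_phylo_tree("(A:1,B:1,C:1,D:1,E:1);"), "non-binary")
})

test_that("foreground flagging locates the terminal branch", {
  tr <- set_foreground(tree5(), "t5")
  expect_length(tr$foreground, 1)
  tip <- which(tr$tip.label == "t5")
  expect_equal(tr$edge[tr$foreground, 2], tip)
  expect_error(set_foreground(tree5(), character(0)), "empty")
  expect_error(set_foreground(tree5(), "nope"), "nope")
})

test_that("gene maps serialize to TSV and back", {
  tr <- tree5()
  a <- simulate_codon_alignment(tr, 2, data.frame(omega = 1, weight = 1),
                                10, code = mito_code, seed = 2)$aln
  f <- tempfile(fileext = ".tsv")
  write_gene_map(a, f)
  expect_identical(read_gene_map(f), attr(a, "gene_map"))
})
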