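test_that("manifest parsing validates structure and flags duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_manifest_csv(path)
  man <- read_probe_manifest(path)
  expect_s3_class(man, "probe_manifest")
  expect_equal(nrow(man), 3)
  expect_equal(attr(man, "probe_length"), 10)

  write_toy_manifest_csv(path, probe_id = c("P1", "P1", "P3"))
  expect_error(read_probe_manifest(path), "P1")

  write_toy_manifest_csv(path, seqs = c("ACGTACGTAC", "TTTTGGGGXC",
                                        "CCCCAAAATT"))
  expect_error(read_probe_manifest(path), "P2")

  write_toy_manifest_csv(path, seqs = c("ACGT", "TTTTGGGGCC", "CCCCAAAATT"))
  expect_error(read_probe_manifest(path), "length")

  # identical sequence under two ids parses but warns, naming both ids
  write_toy_manifest_csv(path, seqs = c("ACGTACGTAC", "ACGTACGTAC",
                                        "CCCCAAAATT"))
  expect_warning(man2 <- read_probe_manifest(path), "P1/P2")
  expect_equal(nrow(man2), 3)

  df <- data.frame(probe_id = "Q", gene_symbol = "G", sequence = "acgt")
  expect_equal(probe_manifest(df)$sequence, "ACGT")
  write.csv(data.frame(probe_id = "P1", sequence = "ACGT"), path,
            row.names = FALSE)
  expect_error(read_probe_manifest(path), "gene_symbol")
})

test_that("read assignment follows Hamming distance and tie rules", {
  man <- toy_manifest()
  exact <- assign_reads(c(r1 = "ACGTACGTAC"), man, max_mismatch = 2)
  expect_equal(exact$probe_id, "P1")
  expect_equal(exact$mismatches, 0L)
  expect_equal(exact$status, "assigned")

  # one mismatch, still assigned with the distance recorded
  one <- assign_reads(mutate_at("ACGTACGTAC", 3), man, max_mismatch = 2)
  expect_equal(one$probe_id, "P1")
  expect_equal(one$mismatches, 1L)

  # beyond tolerance
  far <- assign_reads(mutate_at("ACGTACGTAC", 1:3), man, max_mismatch = 2)
  expect_equal(far$status, "unassigned")

  # equidistant between probes of two different genes: ambiguous
  man2 <- probe_manifest(tibble::tibble(
    probe_id = c("Pa", "Pb"), gene_symbol = c("A", "B"),
    sequence = c("AAAAAAAAAA", "AAAAAAAATT")  # distance 2 apart
  ))
  mid <- assign_reads("AAAAAAAAAT", man2, max_mismatch = 2)  # distance 1 to each
  expect_equal(mid$status, "ambiguous")

  # equidistant between two probes of the same gene: assigned to the gene
  man3 <- probe_manifest(tibble::tibble(
    probe_id = c("Pa", "Pb"), gene_symbol = c("A", "A"),
    sequence = c("AAAAAAAAAA", "AAAAAAAATT")
  ))
  same <- assign_reads("AAAAAAAAAT", man3, max_mismatch = 2)
  expect_equal(same$status, "assigned")
  expect_equal(same$gene_symbol, "A")

  # reads shorter than the probe length are flagged
  shrt <- assign_reads("ACGT", man)
  expect_equal(shrt$status, "short")

  # only the first L bases matter
  long <- assign_reads(paste0("ACGTACGTAC", "GGGGG"), man)
  expect_equal(long$probe_id, "P1")
})

test_that("reads drawn from known probes with <=1 substitution are all recovered", {
  man <- make_manifest(12, L = 30, seed = 5)
  set.seed(7)
  src <- sample(man$probe_id, 120, replace = TRUE)
  reads <- vapply(src, function(pid) {
    s <- man$sequence[man$probe_id == pid]
    if (runif(1) < 0.5) s else mutate_at(s, sample.int(30, 1))
  }, character(1))
  asn <- assign_reads(unname(reads), man, max_mismatch = 1)
  expect_true(all(asn$status == "assigned"))
  expect_equal(asn$probe_id, unname(src))
})

test_that("directory counting matches simulated truth and conserves reads", {
  man <- make_manifest(6, L = 24, seed = 11)
  dir <- withr::local_tempdir()
  comp <- list(
    s1 = setNames(c(40L, 30L, 30L), man$probe_id[1:3]),
    s2 = setNames(c(50L, 50L), man$probe_id[c(4, 6)])
  )
  truth <- simulate_fastq(man, comp, error_rate = 0, dir = dir, seed = 2)
  res <- count_fastq_dir(dir, man, max_mismatch = 2)

  m <- as.matrix(res$probe_counts[-(1:2)])
  rownames(m) <- res$probe_counts$probe_id
  expect_equal(unname(colSums(m)), c(100, 100))
  for (i in seq_len(nrow(truth))) {
    expect_equal(m[truth$probe_id[i], truth$sample_id[i]],
                 truth$n_reads[i], ignore_attr = TRUE)
  }
  # conservation: assigned + ambiguous + unassigned + short = total
  with(res$summary, expect_equal(assigned + ambiguous + unassigned + short,
                                 total))

  # determinism: same inputs, byte-identical result
  res2 <- count_fastq_dir(dir, man, max_mismatch = 2)
  expect_identical(res$gene_counts, res2$gene_counts)

  # oracle equivalence at max_mismatch = 0: plain hash lookup of prefixes
  res0 <- count_fastq_dir(dir, man, max_mismatch = 0)
  for (f in list.files(dir, full.names = TRUE)) {
    lines <- readLines(f)
    prefixes <- substr(lines[seq(2, length(lines), by = 4)], 1, 24)
    oracle <- table(factor(man$probe_id[match(prefixes, man$sequence)],
                           levels = man$probe_id))
    sid <- sub("\\.fastq$", "", basename(f))
    m0 <- as.matrix(res0$probe_counts[-(1:2)])
    expect_equal(unname(m0[, sid]), as.integer(oracle))
  }
})

test_that("gene-level counts sum probes sharing a gene symbol", {
  man <- make_manifest(4, L = 20, n_genes = 3, seed = 13)  # GENE001 has 2 probes
  dir <- withr::local_tempdir()
  comp <- list(s1 = setNames(c(10L, 5L, 7L, 20L), man$probe_id))
  simulate_fastq(man, comp, error_rate = 0, dir = dir, seed = 3)
  res <- count_fastq_dir(dir, man)
  g <- res$gene_counts
  two_probe_gene <- names(which(table(man$gene_symbol) == 2))
  probes <- man$probe_id[man$gene_symbol == two_probe_gene]
  expect_equal(g$s1[g$gene == two_probe_gene],
               sum(comp$s1[probes]))
  expect_equal(sum(g$s1), sum(comp$s1))
})

test_that("counting handles empty and ill-formed FASTQ inputs", {
  man <- make_manifest(3, L = 20, seed = 17)
  dir <- withr::local_tempdir()
  simulate_fastq(man, list(ok = setNames(5L, man$probe_id[1])),
                 error_rate = 0, dir = dir, seed = 1)
  file.create(file.path(dir, "empty.fastq"))
  expect_warning(res <- count_fastq_dir(dir, man), "empty.fastq")
  m <- as.matrix(res$probe_counts[-(1:2)])
  expect_equal(sum(m[, "empty"]), 0)
  expect_equal(sum(m[, "ok"]), 5)

  writeLines(c("@r1", "ACGT"), file.path(dir, "bad.fastq"))
  expect_error(suppressWarnings(count_fastq_dir(dir, man)), "bad.fastq")
  expect_error(count_fastq_dir(withr::local_tempdir(), man), "no FASTQ")
})

test_that("merging per-sample count tables imputes zeros and checks probes", {
  man <- toy_manifest()
  t1 <- tibble::tibble(probe_id = c("P1", "P2", "P3"), count = c(5L, 3L, 2L))
  t2 <- tibble::tibble(probe_id = c("P1", "P3"), count = c(7L, 1L))  # P2 absent
  merged <- merge_count_tables(list(a = t1, b = t2), man)
  m <- as.matrix(merged$probe_counts[-(1:2)])
  expect_equal(unname(m[, "a"]), c(5, 3, 2))
  expect_equal(unname(m[, "b"]), c(7, 0, 1))
  expect_equal(colnames(m), c("a", "b"))

  bad <- tibble::tibble(probe_id = "NOPE", count = 1L)
  expect_error(merge_count_tables(list(a = t1, z = bad), man), "NOPE")

  # many single-column tables: column count and totals preserved
  tabs <- lapply(1:384, function(i) {
    tibble::tibble(probe_id = "P2", count = i)
  })
  big <- merge_count_tables(tabs, man)
  mb <- as.matrix(big$probe_counts[-(1:2)])
  expect_equal(ncol(mb), 384)
  expect_equal(sum(mb), sum(1:384))
})
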