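test_that("feature tables load in both orientations and reject bad cells", {
  p <- write_tmp(c("id\tf1\tf2", "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"))
  ft <- read_feature_table(p, "samples_in_rows")
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(ft$values["s2", "f2"], 4)
  expect_equal(ft$transform_tag, "raw")

  tf <- read_feature_table(p, "features_in_rows")
  expect_identical(tf$values, t(ft$values))

  bad <- write_tmp(c("id\tf1\tf2", "s1\t1\tabc"))
  err <- expect_error(read_feature_table(bad), "abc")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "f2")

  dup <- write_tmp(c("id\tf1", "s1\t1", "s1\t2"))
  expect_error(read_feature_table(dup), "duplicated")
  empty <- write_tmp("id\tf1")
  expect_error(read_feature_table(empty), "empty")
})

test_that("csv and tsv delimiters are sniffed from extension and content", {
  p_csv <- write_tmp(c("id,f1,f2", "s1,1,2"), ext = "csv")
  expect_equal(unname(read_feature_table(p_csv)$values[1, 2]), 2)
  # unknown extension falls back to sniffing the first line
  p_sniff <- write_tmp(c("id\tf1", "s1\t7"), ext = "dat")
  expect_equal(unname(read_feature_table(p_sniff)$values[1, 1]), 7)
})

test_that("write/read round-trip preserves integers exactly and reals to 1e-12", {
  ints <- make_ft(matrix(c(0, 5, 123456789, 2, 7, 9), 2, 3))
  p <- tempfile(fileext = ".tsv")
  write_feature_table(ints, p)
  expect_identical(read_feature_table(p)$values, ints$values)

  reals <- with_seed(42, make_ft(matrix(rlnorm(12) * 1e3, 3, 4)))
  p2 <- tempfile(fileext = ".tsv")
  write_feature_table(reals, p2)
  back <- read_feature_table(p2)
  expect_lt(max(abs(back$values - reals$values) / abs(reals$values)), 1e-12)

  # transformed tables (negative entries) round-trip with their tag
  pt <- pareto_scale(with_seed(1, make_ft(matrix(rnorm(20), 5, 4))))
  p3 <- tempfile(fileext = ".tsv")
  write_feature_table(pt, p3)
  back3 <- read_feature_table(p3, transform_tag = "pareto")
  expect_lt(max(abs(back3$values - pt$values)), 1e-12)
})

test_that("metadata columns are auto-typed with hint precedence", {
  p <- write_tmp(c("id\tgroup\tcalprotectin\tdose",
                   "s1\tCD\t150.5\t1",
                   "s2\tH\t20\t2",
                   "s3\tCD\t\t1"))
  md <- read_sample_metadata(p)
  expect_s3_class(md$group, "factor")
  expect_equal(nlevels(md$group), 2L)
  expect_type(md$calprotectin, "double")
  expect_true(is.na(md["s3", "calprotectin"]))

  md2 <- read_sample_metadata(p, type_hints = list(dose = "categorical"))
  expect_s3_class(md2$dose, "factor")
  expect_setequal(levels(md2$dose), c("1", "2"))

  dup <- write_tmp(c("id\tg", "s1\ta", "s1\tb"))
  expect_error(read_sample_metadata(dup), "duplicated")
})

test_that("mapping tables dedupe pairs and enforce unique contig assignment", {
  p <- write_tmp(c("c1\tk1", "c2\tk1", "c3\tk2", "c4\tk2", "c4\tk2"))
  m <- read_mapping(p, role = "contig_to_cluster")
  expect_equal(nrow(m), 4L)

  conflict <- write_tmp(c("c1\tk1", "c1\tk2"))
  expect_error(read_mapping(conflict, role = "contig_to_cluster"), "c1")
  # many-to-many is fine for pathway membership
  m2 <- read_mapping(conflict, role = "ko_to_pathway")
  expect_equal(nrow(m2), 2L)
})

test_that("newick trees parse with path lengths and errors carry position info", {
  p <- write_tmp("((A:1,B:1):1,C:2);", ext = "nwk")
  tr <- read_newick_tree(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  d <- cophenetic_matrix(tr)
  expect_equal(d["A", "B"], 2)

  p2 <- write_tmp("(A:1,B:1);", ext = "nwk")
  expect_equal(cophenetic_matrix(read_newick_tree(p2))["A", "B"], 2)

  bad <- write_tmp("((A,B)", ext = "nwk")
  expect_error(suppressWarnings(read_newick_tree(bad)))
})

test_that("tip-to-tip path lengths survive re-serialization", {
  tr <- simulate_tree(12, seed = 7)
  p <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, p)
  tr2 <- read_newick_tree(p)
  d1 <- cophenetic_matrix(tr)
  d2 <- cophenetic_matrix(tr2)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-8)
})

test_that("harmonization intersects, sorts, reports and is idempotent", {
  t1 <- make_ft(matrix(1:6, 3, 2), samples = c("S3", "S1", "S2"))
  t2 <- make_ft(matrix(1:6, 3, 2), samples = c("S2", "S3", "S4"))
  md <- structure(data.frame(g = factor(c("a", "b", "c")),
                             row.names = c("S2", "S3", "S9")),
                  class = c("sample_metadata", "data.frame"))
  h <- harmonize_samples(list(a = t1, b = t2), md)
  expect_identical(sample_ids(h$tables$a), c("S2", "S3"))
  expect_identical(sample_ids(h$tables$b), c("S2", "S3"))
  expect_identical(rownames(h$metadata), c("S2", "S3"))
  expect_setequal(h$report$dropped_sample, c("S1", "S4", "S9"))
  # values follow their sample ids
  expect_equal(h$tables$a$values["S2", ], t1$values["S2", ])

  h2 <- harmonize_samples(h$tables, h$metadata)
  expect_identical(h2$tables$a$values, h$tables$a$values)
  expect_equal(nrow(h2$report), 0L)

  t3 <- make_ft(matrix(1:2, 1, 2), samples = "SX")
  expect_error(harmonize_samples(list(t1, t3)), "no sample ids shared")
})
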