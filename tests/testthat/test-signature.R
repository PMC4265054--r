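make_rank1 <- function(m, n, scale = 5, seed = 1) {
  set.seed(seed)
  u <- rnorm(m); u <- u / sqrt(sum(u^2))
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  vals <- scale * tcrossprod(u, v)
  dimnames(vals) <- list(sprintf("g%03d", 1:m), sprintf("s%03d", 1:n))
  list(em = expression_matrix(vals), u = u, v = v)
}

test_that("an exact rank-1 matrix yields its generating triplet", {
  r1 <- make_rank1(30, 8, scale = 5)
  model <- extract_signature(r1$em)
  expect_equal(model$s1, 5, tolerance = 1e-10)
  expect_equal(variance_explained(model), 1, tolerance = 1e-12)
  # u1 collinear with the generator and with the signature profile
  expect_equal(abs(sum(model$u1 * r1$u)), 1, tolerance = 1e-10)
  cosine <- sum(model$signature_profile * model$u1) /
    sqrt(sum(model$signature_profile^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-10)
  # unit norms and sign convention
  expect_equal(sum(model$u1^2), 1, tolerance = 1e-10)
  expect_equal(sum(model$v1^2), 1, tolerance = 1e-10)
  expect_gt(model$u1[which.max(abs(model$u1))], 0)
})

test_that("the first triplet matches a power-iteration oracle on small matrices", {
  for (seed in 1:12) {
    set.seed(seed)
    nr <- sample(2:10, 1)
    nc <- sample(2:10, 1)
    em <- random_expr_matrix(nr, nc, seed = seed * 100)
    model <- extract_signature(em)
    orc <- power_iteration_svd(em$values, k = min(nr, nc))
    o1 <- orient_like_package(orc$u[, 1], orc$v[, 1])
    expect_equal(model$s1, orc$d[1], tolerance = 1e-8)
    expect_equal(unname(model$u1), o1$u, tolerance = 1e-7)
    expect_equal(unname(model$v1), o1$v, tolerance = 1e-7)
    expect_equal(variance_explained(model), orc$d[1]^2 / sum(orc$d^2),
                 tolerance = 1e-8)
  }
})

test_that("variance fraction handles degenerate spectra", {
  # two equal singular values, rest zero -> exactly one half
  vals <- diag(c(3, 3, 0, 0))
  dimnames(vals) <- list(paste0("g", 1:4), paste0("s", 1:4))
  expect_equal(variance_explained(extract_signature(expression_matrix(vals))),
               0.5)
  # all-zero matrix has no signature
  vals0 <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_error(extract_signature(expression_matrix(vals0)), "no signature")
  # missing values are redirected to imputation
  vals0[1, 1] <- NA; vals0[2, 2] <- 1
  expect_error(extract_signature(expression_matrix(vals0)), "impute")
})

test_that("extraction is scale-equivariant", {
  em <- random_expr_matrix(20, 10, seed = 7)
  m1 <- extract_signature(em)
  em2 <- expression_matrix(-2.5 * em$values)
  m2 <- extract_signature(em2)
  expect_equal(m2$s1, 2.5 * m1$s1, tolerance = 1e-10)
  expect_equal(abs(sum(m1$u1 * m2$u1)), 1, tolerance = 1e-10)
})

test_that("similarity scores are inner products with the unit signature", {
  em <- random_expr_matrix(50, 6, seed = 3)
  model <- extract_signature(em)
  # a column equal to u1 scores 1; an orthogonal column scores 0
  probe <- cbind(u = unname(model$u1), orth = 0)
  probe[1:2, "orth"] <- c(model$u1[[2]], -model$u1[[1]])
  dimnames(probe) <- list(names(model$u1), c("asU1", "orth"))
  sc <- similarity_scores(expression_matrix(probe), model)
  expect_equal(sc$score[sc$sample_id == "asU1"], 1, tolerance = 1e-10)
  expect_equal(sc$score[sc$sample_id == "orth"], 0, tolerance = 1e-10)
})

test_that("profile correlation is exact at the poles and small under the null", {
  em <- random_expr_matrix(1000, 4, seed = 21)
  model <- extract_signature(em)
  probe <- cbind(model$signature_profile, -model$signature_profile)
  set.seed(99)
  probe <- cbind(probe, rnorm(1000))
  dimnames(probe) <- list(model$gene_ids, c("plus", "minus", "random"))
  rr <- correlate_with_signature(expression_matrix(probe), model)
  expect_equal(rr$r[rr$sample_id == "plus"], 1, tolerance = 1e-12)
  expect_equal(rr$r[rr$sample_id == "minus"], -1, tolerance = 1e-12)
  expect_lt(abs(rr$r[rr$sample_id == "random"]), 0.1)
})

test_that("first-mode removal is an exact orthogonal decomposition", {
  # exact rank-1 input -> zero matrix
  r1 <- make_rank1(12, 5)
  model <- extract_signature(r1$em)
  star <- remove_first_mode(r1$em, model)
  expect_lt(max(abs(star$values)), 1e-10)

  # explicit two-mode matrix -> the second mode survives untouched
  u <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  v <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  vals <- 7 * tcrossprod(u[, 1], v[, 1]) + 2 * tcrossprod(u[, 2], v[, 2])
  dimnames(vals) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:6))
  em <- expression_matrix(vals)
  star <- remove_first_mode(em, extract_signature(em))
  expect_equal(unname(star$values), 2 * tcrossprod(u[, 2], v[, 2]),
               tolerance = 1e-10)

  # random matrix: reconstruction, orthogonality, spectral shift
  em <- random_expr_matrix(100, 30, seed = 13)
  model <- extract_signature(em)
  star <- remove_first_mode(em, model)
  recon <- star$values + model$s1 * tcrossprod(model$u1, model$v1)
  expect_lt(max(abs(recon - em$values)), 1e-10)
  expect_lt(max(abs(crossprod(star$values, model$u1))), 1e-8)
  expect_equal(svd(star$values)$d[1], svd(em$values)$d[2], tolerance = 1e-8)

  # dimension mismatch is refused
  expect_error(remove_first_mode(random_expr_matrix(10, 3, seed = 1), model),
               "id mismatch")
})

test_that("Gram-Schmidt profile transformation removes exactly the projection", {
  em <- random_expr_matrix(40, 8, seed = 31)
  model <- extract_signature(em)

  # multiples of u1 vanish
  p <- 3.2 * model$u1
  expect_lt(max(abs(remove_signature_from_profile(p, model))), 1e-10)

  # random profile: orthogonal residual + exact reconstruction
  set.seed(8)
  p <- setNames(rnorm(40), model$gene_ids)
  out <- remove_signature_from_profile(p, model)
  expect_lt(abs(sum(out * model$u1)), 1e-8)
  proj <- sum(p * model$u1)
  expect_equal(out + proj * model$u1, p, tolerance = 1e-10,
               ignore_attr = TRUE)

  # partial overlap: renormalized subset, unmatched genes untouched
  p2 <- setNames(rnorm(25), c(model$gene_ids[1:20], paste0("x", 1:5)))
  out2 <- remove_signature_from_profile(p2, model)
  expect_identical(out2[21:25], p2[21:25])
  expect_setequal(attr(out2, "unmatched"), paste0("x", 1:5))
  u_sub <- model$u1[1:20]
  u_sub <- u_sub / sqrt(sum(u_sub^2))
  expect_lt(abs(sum(out2[1:20] * u_sub)), 1e-8)

  expect_error(
    remove_signature_from_profile(setNames(1:5, paste0("x", 1:5)), model),
    "no genes shared"
  )
})

test_that("robust strain filter requires strictly more than three qualifying transcripts", {
  vals <- matrix(0, 10, 3,
                 dimnames = list(sprintf("g%02d", 1:10), c("four", "three", "none")))
  pv <- matrix(1, 10, 3, dimnames = dimnames(vals))
  vals[1:4, "four"] <- 1; pv[1:4, "four"] <- 0.01
  vals[1:3, "three"] <- 1; pv[1:3, "three"] <- 0.01
  em <- expression_matrix(vals, pvalues = pv)
  expect_identical(robust_strain_filter(em), "four")
  expect_error(robust_strain_filter(expression_matrix(vals)), "p-values")
  # all-zero matrix keeps nothing
  em0 <- expression_matrix(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"), c("x", "y"))),
                           pvalues = matrix(0.001, 2, 2,
                                            dimnames = list(c("a", "b"),
                                                            c("x", "y"))))
  expect_length(robust_strain_filter(em0), 0)
})

test_that("signature models survive JSON serialization", {
  em <- random_expr_matrix(15, 6, seed = 2)
  model <- extract_signature(em)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_equal(back$u1, model$u1)
  expect_equal(back$s1, model$s1)
  expect_equal(back$signature_profile, model$signature_profile)
  # a reloaded model drives the same transformation
  p <- setNames(rnorm(15), model$gene_ids)
  expect_equal(remove_signature_from_profile(p, back),
               remove_signature_from_profile(p, model))
})
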