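test_that("CSC and CSR column extraction match the storage definition", {
  csc <- sparseEncoding("csc", c(3, 2), data = c(5, 7), indices = c(0, 2),
                        indptr = c(0, 1, 2))
  expect_identical(sparseColumn(csc, 0), c(5, 0, 0))
  expect_identical(sparseColumn(csc, 1), c(0, 0, 7))

  csr <- sparseEncoding("csr", c(3, 2), data = c(5, 7), indices = c(0, 1),
                        indptr = c(0, 1, 1, 2))
  expect_identical(sparseColumn(csr, 1), c(0, 0, 7))
  expect_identical(sparseColumn(csr, 0), c(5, 0, 0))
})

test_that("column index bounds are enforced", {
  csc <- sparseEncoding("csc", c(3, 2), data = c(5, 7), indices = c(0, 2),
                        indptr = c(0, 1, 2))
  expect_error(sparseColumn(csc, 2), "out of range")
  expect_error(sparseColumn(csc, -1), "out of range")
})

test_that("malformed encodings are rejected", {
  expect_error(sparseEncoding("csc", c(3, 2), 1, 0, c(0, 1)), "indptr has length")
  expect_error(sparseEncoding("csc", c(3, 2), 1, 0, c(1, 1, 1)),
               "start at 0")
  expect_error(sparseEncoding("csc", c(3, 2), 1, 5, c(0, 1, 1)),
               "minor-dimension bounds")
  expect_error(sparseEncoding("csc", c(3, 2), c(1, 2), c(0, 1), c(0, 2, 1)),
               "non-decreasing")
})

test_that("CSC access cost is proportional to the column, CSR to nnz", {
  csc <- sparseEncoding("csc", c(10, 3), data = c(1, 2, 3, 4),
                        indices = c(0, 5, 9, 2), indptr = c(0, 3, 3, 4))
  io <- new.env(); io$io <- 0
  sparseColumn(csc, 1, io)                    # empty column
  expect_identical(io$io, 2)                  # two indptr entries only
  sparseColumn(csc, 0, io)
  expect_identical(io$io, 2 + 2 + 2 * 3)      # plus 3 values + 3 indices

  csr <- sparseEncoding("csr", c(4, 3), data = 1:4, indices = c(0, 1, 2, 0),
                        indptr = c(0, 2, 3, 3, 4))
  io$io <- 0
  sparseColumn(csr, 0, io)
  expect_gte(io$io, length(csr$indices))      # full scan is unavoidable
})

test_that("sparse columns agree with a densify-then-index oracle", {
  set.seed(11)
  for (rep in 1:1000) {
    nr <- sample(1:8, 1); nc <- sample(1:8, 1)
    dense <- matrix(rbinom(nr * nc, 1, 0.4) * round(runif(nr * nc, 1, 9)),
                    nr, nc)
    for (order in c("csr", "csc")) {
      m <- as(as(Matrix::Matrix(if (order == "csc") dense else t(dense),
                                sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
      enc <- sparseEncoding(order, c(nr, nc), data = m@x, indices = m@i,
                            indptr = m@p)
      j <- sample(nc, 1) - 1L
      expect_identical(sparseColumn(enc, j), as.numeric(dense[, j + 1L]),
                       label = sprintf("%s %dx%d col %d rep %d",
                                       order, nr, nc, j, rep))
    }
  }
})
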