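test_that("credit assignment implements the tie-tolerant argmax rule", {
  p <- c(CN = 0.257, AD = 0.743, BVFTD = 0, SD = 0, PNFA = 0, PSP = 0,
         DLB = 0)
  expect_equal(assignCredit(p),
               c(CN = 0, AD = 1, BVFTD = 0, SD = 0, PNFA = 0, PSP = 0,
                 DLB = 0))
  p3 <- c(CN = 0.3, AD = 0.05, BVFTD = 0.3, SD = 0.05, PNFA = 0, PSP = 0.3,
          DLB = 0)
  cr <- assignCredit(p3)
  expect_equal(unname(cr[c("CN", "BVFTD", "PSP")]), rep(1 / 3, 3))
  expect_equal(sum(cr), 1)
  # tolerance folds near-equal values into the tie set
  p2 <- c(A = 0.3000000001, B = 0.3, C = 0.1)
  expect_equal(unname(assignCredit(p2, tieTolerance = 1e-3)[1:2]),
               c(0.5, 0.5))
  expect_equal(unname(assignCredit(p2, tieTolerance = 1e-12)),
               c(1, 0, 0))
  # reported-precision mode rounds before comparing
  expect_equal(unname(assignCredit(p2, digits = 3)[1:2]), c(0.5, 0.5))
})

test_that("per-case scoring gives 1, 1/k or 0", {
  uniq <- assignCredit(c(CN = 0.2, AD = 0.8))
  expect_equal(scoreCase(uniq, "AD"), 1)
  expect_equal(scoreCase(uniq, "CN"), 0)
  tie <- assignCredit(c(CN = 0.5, AD = 0.5))
  expect_equal(scoreCase(tie, "AD"), 0.5)
  tri <- assignCredit(c(CN = 0.3, AD = 0.3, DLB = 0.3, SD = 0.1))
  expect_equal(scoreCase(tri, "SD"), 0)
})

test_that("fractional confusion matrix matches the per-case loop oracle", {
  for (seed in c(1, 2, 3)) {
    at <- randomStudy(10, tieRate = 0.5, seed = seed)
    expect_equal(fractionalConfusion(at, "R1"), bruteConfusion(at, "R1"),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # hand case: one unique-max AD and one CN/AD tie among true AD subjects
  arr <- array(0, dim = c(2, 1, 7), dimnames = list(c("a", "b"), "r", CODES))
  arr["a", 1, ] <- c(0.1, 0.9, 0, 0, 0, 0, 0)
  arr["b", 1, ] <- c(0.45, 0.45, 0.1, 0, 0, 0, 0)
  at <- AssessmentTable(arr, truth = c("AD", "AD"))
  m <- fractionalConfusion(at, "r")
  expect_equal(unname(m["AD", c("AD", "CN")]), c(1.5, 0.5))
  # conservation: total mass equals N
  at2 <- randomStudy(17, tieRate = 0.8, seed = 9)
  expect_equal(sum(fractionalConfusion(at2, "R1")), 17)
})

test_that("binary metrics count fractional credit and off-pair mass", {
  # 2 AD subjects: one correct, one CN/AD tie -> sensitivity 1.5/2
  arr <- array(0, dim = c(4, 1, 7), dimnames = list(NULL, "r", CODES))
  arr[1, 1, ] <- c(0.1, 0.9, 0, 0, 0, 0, 0)
  arr[2, 1, ] <- c(0.45, 0.45, 0.1, 0, 0, 0, 0)
  arr[3, 1, ] <- c(0.9, 0.1, 0, 0, 0, 0, 0)
  arr[4, 1, ] <- c(0.8, 0.2, 0, 0, 0, 0, 0)
  at <- AssessmentTable(arr, truth = c("AD", "AD", "CN", "CN"))
  cl <- classificationMetrics(fractionalConfusion(at, "r"))
  expect_equal(cl$sensitivity$estimate, 0.75)
  expect_equal(cl$specificity$estimate, 1)
  expect_equal(cl$accuracy$estimate, 3.5 / 4)
  # mass on DLB for an AD subject contributes nothing to sensitivity
  arr[2, 1, ] <- c(0.1, 0.2, 0, 0, 0, 0, 0.7)
  at2 <- AssessmentTable(arr, truth = c("AD", "AD", "CN", "CN"))
  cl2 <- classificationMetrics(fractionalConfusion(at2, "r"))
  expect_equal(cl2$sensitivity$estimate, 0.5)
  # perfect rater
  arrP <- array(0, dim = c(2, 1, 7), dimnames = list(NULL, "r", CODES))
  arrP[1, 1, "AD"] <- 1; arrP[2, 1, "CN"] <- 1
  clP <- classificationMetrics(
    fractionalConfusion(AssessmentTable(arrP, truth = c("AD", "CN")), "r"))
  expect_equal(clP$accuracy$estimate, 1)
  expect_equal(clP$sensitivity$estimate, 1)
  expect_equal(clP$specificity$estimate, 1)
})

test_that("with no ties every metric equals its classical form exactly", {
  for (seed in 11:13) {
    at <- randomStudy(15, tieRate = 0, seed = seed)
    m <- fractionalConfusion(at, "R1")
    expect_true(all(m == round(m)))   # integer counts
    cl <- classificationMetrics(m)
    ref <- classicalMetrics(at, "R1")
    expect_equal(cl$accuracy$estimate, ref$accuracy)
    expect_equal(cl$sensitivity$estimate, ref$sensitivity)
    expect_equal(cl$specificity$estimate, ref$specificity)
  }
})

test_that("Wilson interval matches its closed form and prop.test", {
  w <- wilsonInterval(5, 10)
  expect_equal(unname(w), c(0.2365931, 0.7634069), tolerance = 1e-6)
  # zero-success boundary: lower 0, upper z^2/(n + z^2)
  z <- qnorm(0.975)
  w0 <- wilsonInterval(0, 10)
  expect_equal(unname(w0), c(0, z^2 / (10 + z^2)), tolerance = 1e-12)
  expect_equal(unname(wilsonInterval(10, 10)["upper"]), 1)
  # integer cases agree with prop.test without continuity correction
  for (s in c(1, 4, 7)) {
    pt <- prop.test(s, 12, correct = FALSE)$conf.int
    expect_equal(unname(wilsonInterval(s, 12)), as.numeric(pt),
                 tolerance = 1e-9)
  }
  # interval always contains the estimate
  for (s in c(0, 0.5, 3.25, 38)) {
    w <- wilsonInterval(s, 38)
    expect_true(w["lower"] <= s / 38 + 1e-12 && s / 38 <= w["upper"] + 1e-12)
  }
})

test_that("weighted F1 follows the stated per-class decomposition", {
  m <- rbind(CN = c(CN = 15, AD = 5, BVFTD = 0, SD = 0, PNFA = 0, PSP = 0,
                    DLB = 0),
             AD = c(CN = 5, AD = 13, BVFTD = 0, SD = 0, PNFA = 0, PSP = 0,
                    DLB = 0))
  expect_equal(weightedF1(m), (20 * 0.75 + 18 * (13 / 18)) / 38,
               tolerance = 1e-12)
  # perfect rater
  mp <- rbind(CN = c(20, 0, 0, 0, 0, 0, 0), AD = c(0, 18, 0, 0, 0, 0, 0))
  colnames(mp) <- CODES; rownames(mp) <- c("CN", "AD")
  expect_equal(weightedF1(mp), 1)
  # everything dumped on one non-pair class
  m0 <- rbind(CN = c(0, 0, 20, 0, 0, 0, 0), AD = c(0, 0, 18, 0, 0, 0, 0))
  colnames(m0) <- CODES; rownames(m0) <- c("CN", "AD")
  expect_equal(weightedF1(m0), 0)
})

test_that("tie-aware kappa reduces to textbook Cohen's kappa and is symmetric", {
  a <- c("CN", "CN", "AD", "AD"); b <- c("CN", "AD", "AD", "AD")
  k <- tieAwareKappa(a, b)
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.5)
  # identity and symmetry
  expect_equal(tieAwareKappa(a, a)$kappa, 1)
  at <- randomStudy(12, nRaters = 2, tieRate = 0.4, seed = 5)
  ka <- tieAwareKappa(creditMatrix(at, "R1"), creditMatrix(at, "R2"))
  kb <- tieAwareKappa(creditMatrix(at, "R2"), creditMatrix(at, "R1"))
  expect_equal(ka$kappa, kb$kappa, tolerance = 1e-12)
  # a half split against a committed label contributes 0.5 agreement
  A <- rbind(c(CN = 0.5, AD = 0.5), c(CN = 1, AD = 0))
  B <- rbind(c(CN = 0, AD = 1), c(CN = 1, AD = 0))
  expect_equal(tieAwareKappa(A, B)$p_o, mean(c(0.5, 1)))
  # degenerate: both always the same single category
  kd <- tieAwareKappa(c("AD", "AD"), c("AD", "AD"))
  expect_true(is.na(kd$kappa))
  expect_match(kd$reason, "degenerate")
})

test_that("no-tie kappa equals the contingency-table formula on random data", {
  for (seed in 21:23) {
    at <- randomStudy(20, nRaters = 2, tieRate = 0, seed = seed)
    predOf <- function(r) apply(raterProbs(at, r), 1L,
                                function(v) CODES[which.max(v)])
    a <- predOf("R1"); b <- predOf("R2")
    tab <- table(factor(a, CODES), factor(b, CODES))
    po <- sum(diag(tab)) / sum(tab)
    pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
    kClassic <- (po - pe) / (1 - pe)
    k <- tieAwareKappa(creditMatrix(at, "R1"), creditMatrix(at, "R2"))
    expect_equal(k$kappa, kClassic, tolerance = 1e-12)
  }
})
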