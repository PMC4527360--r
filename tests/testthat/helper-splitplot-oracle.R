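# independently coded cell-means oracle for the balanced split-plot layout:
# whole plots = year x replicate, subplot factor = producer
splitPlotOracle <- function(y, year, rep_, prod_) {
  year <- as.character(year); rep_ <- as.character(rep_)
  prod_ <- as.character(prod_)
  n <- length(y); g <- mean(y)
  ny <- length(unique(year)); nr <- length(unique(rep_))
  np <- length(unique(prod_))
  mY <- tapply(y, year, mean); mR <- tapply(y, rep_, mean)
  mP <- tapply(y, prod_, mean)
  mYR <- tapply(y, list(year, rep_), mean)
  ssY <- nr * np * sum((mY - g)^2)
  ssR <- ny * np * sum((mR - g)^2)
  ssWP <- np * sum((mYR - outer(mY, mR, "+") + g)^2)
  ssP <- ny * nr * sum((mP - g)^2)
  ssTot <- sum((y - g)^2)
  ssE <- ssTot - ssY - ssR - ssWP - ssP
  dfY <- ny - 1; dfR <- nr - 1; dfWP <- (ny - 1) * (nr - 1); dfP <- np - 1
  dfE <- n - 1 - dfY - dfR - dfWP - dfP
  msY <- ssY / dfY; msR <- ssR / dfR; msWP <- ssWP / dfWP
  msP <- ssP / dfP; msE <- ssE / dfE
  list(SS = c(year = ssY, replicate = ssR, wholeplot_error = ssWP,
              producer = ssP, residual = ssE),
       df = c(dfY, dfR, dfWP, dfP, dfE),
       F = c(year = msY / msWP, replicate = msR / msWP,
             producer = msP / msE),
       p = c(year = pf(msY / msWP, dfY, dfWP, lower.tail = FALSE),
             producer = pf(msP / msE, dfP, dfE, lower.tail = FALSE)))
}

balancedDesign <- function() {
  d <- expand.grid(replicate = 1:3, vintage = c(2006, 2007, 2008),
                   vineyard = c("AM", "BA", "BM", "CS", "FA", "MN", "PM"),
                   stringsAsFactors = FALSE)
  rownames(d) <- sprintf("%s_%d_r%d", d$vineyard, d$vintage, d$replicate)
  studyDesign(transform(d, stage = 3))
}
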