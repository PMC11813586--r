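# Generates inst/extdata/dip_null_table.csv: Monte Carlo quantiles of the
# dip statistic for uniform samples, 10,000 replicates per sample size,
# fixed seed.  Rerun with: Rscript data-raw/dip_null_table.R
library(protodom)

ns <- c(4, 5, 6, 8, 10, 12, 15, 20, 25, 30, 40, 50, 70, 100, 150,
        200, 300, 500, 700, 1000, 1500, 2000)
B <- 10000L
probs <- seq(0.005, 0.995, by = 0.005)

set.seed(20260920)
rows <- lapply(ns, function(n) {
  d <- protodom:::.dip_null_cpp(n, B)
  q <- signif(quantile(d, probs, names = FALSE, type = 7), 6)
  message("n = ", n, " done")
  c(n, q)
})
tab <- do.call(rbind, rows)
colnames(tab) <- c("n", paste0("p", format(probs, trim = TRUE)))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(as.data.frame(tab), "inst/extdata/dip_null_table.csv",
          row.names = FALSE, quote = FALSE)
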