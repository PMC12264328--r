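# First-order statistics of one slice ROI. Entropy and Uniformity work on the
# discretized gray levels; all other features use the (standardized) raw
# intensities. Energy/TotalEnergy are computed without a voxel-intensity
# shift, so standardized (zero-centred) inputs are legitimate.

firstorder_slice <- function(vals, disc_vals, vox_vol, eps = .Machine$double.eps) {
  n <- length(vals)
  m <- mean(vals)
  qs <- quantile(vals, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  p10 <- qs[1]; p90 <- qs[5]
  robust <- vals[vals >= p10 & vals <= p90]
  pv <- tabulate(disc_vals) / n
  pv <- pv[pv > 0]
  m2 <- mean((vals - m)^2)
  sk <- if (m2 == 0) 0 else mean((vals - m)^3) / m2^1.5
  ku <- if (m2 == 0) 0 else mean((vals - m)^4) / m2^2
  c(
    Energy = sum(vals^2),
    TotalEnergy = vox_vol * sum(vals^2),
    Entropy = -sum(pv * log2(pv + eps)),
    Minimum = min(vals),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(vals),
    Mean = m,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - m)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = m2,
    Uniformity = sum(pv^2)
  )
}
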