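# Independent plain-R reference implementations, written directly from the
# update equations, used as oracles against the package's compiled path.

oracle_filter <- function(u_c, u_s, omega, sigma2_0, mu2_0 = 0,
                          variant = "2HGF", kappa = 1, mu3_0 = 1,
                          sigma3_0 = 0.1, theta = exp(-6), clamp = 36) {
  n3 <- grepl("^3", variant)
  pfb <- grepl("precfb", variant)
  n <- length(u_c)
  st <- list(
    c = list(mu2 = mu2_0, s2 = sigma2_0, mu3 = mu3_0, s3 = sigma3_0),
    s = list(mu2 = mu2_0, s2 = sigma2_0, mu3 = mu3_0, s3 = sigma3_0))
  out <- list(mu1hat_c = numeric(n), mu1hat_s = numeric(n),
              pi1hat_c = numeric(n), pi1hat_s = numeric(n),
              delta1_c = numeric(n), delta1_s = numeric(n),
              rel_c = numeric(n), rel_s = numeric(n))
  sig <- function(x) 1 / (1 + exp(-max(min(x, clamp), -clamp)))
  for (k in seq_len(n)) {
    pred <- lapply(st, function(b) {
      v <- if (n3) exp(kappa * b$mu3 + omega) else exp(omega)
      mu1hat <- sig(b$mu2)
      list(v = v, s2hat = b$s2 + v, mu1hat = mu1hat,
           pi1hat = 1 / (mu1hat * (1 - mu1hat)))
    })
    rc <- pred$c$pi1hat / (pred$c$pi1hat + pred$s$pi1hat)
    out$mu1hat_c[k] <- pred$c$mu1hat; out$mu1hat_s[k] <- pred$s$mu1hat
    out$pi1hat_c[k] <- pred$c$pi1hat; out$pi1hat_s[k] <- pred$s$pi1hat
    out$delta1_c[k] <- u_c[k] - pred$c$mu1hat
    out$delta1_s[k] <- u_s[k] - pred$s$mu1hat
    out$rel_c[k] <- rc; out$rel_s[k] <- 1 - rc
    for (b in c("c", "s")) {
      u <- if (b == "c") u_c[k] else u_s[k]
      rel <- if (b == "c") rc else 1 - rc
      p <- pred[[b]]
      d1 <- u - p$mu1hat
      pi2 <- 1 / p$s2hat + 1 / p$pi1hat
      w <- if (pfb) 2 * rel else 1
      mu2_new <- st[[b]]$mu2 + w * d1 / pi2
      s2_new <- max(1 / pi2, 1e-12)
      if (n3) {
        w2 <- p$v / p$s2hat
        d2 <- (s2_new + (mu2_new - st[[b]]$mu2)^2) / p$s2hat - 1
        pi3 <- 1 / (st[[b]]$s3 + theta) +
          kappa^2 / 2 * w2 * (w2 + (2 * w2 - 1) * d2)
        pi3 <- max(pi3, 1e-6)
        st[[b]]$mu3 <- st[[b]]$mu3 + kappa / (2 * pi3) * w2 * d2
        st[[b]]$s3 <- 1 / pi3
      }
      st[[b]]$mu2 <- mu2_new
      st[[b]]$s2 <- s2_new
    }
  }
  out
}

oracle_logrt <- function(orc, task, b, variant = "RelPE+IrrelBias") {
  relpe <- variant %in% c("RelPE", "RelPE+IrrelBias")
  irrb <- variant %in% c("IrrelBias", "RelPE+IrrelBias")
  n <- nrow(task)
  pred <- numeric(n)
  for (k in seq_len(n)) {
    pe <- if (relpe) {
      (orc$rel_c[k] * abs(orc$delta1_c[k]) +
         orc$rel_s[k] * abs(orc$delta1_s[k])) / 2
    } else (abs(orc$delta1_c[k]) + abs(orc$delta1_s[k])) / 2
    wc <- if (irrb) orc$rel_s[k] else 1
    ws <- if (irrb) orc$rel_c[k] else 1
    pred[k] <- b["beta0"] + b["beta1"] * pe -
      wc * (b["beta2"] * (task$color[k] == "colorful") +
              b["beta3"] * (task$color[k] == "grey")) -
      ws * (b["beta4"] * (task$shape[k] == "square") +
              b["beta5"] * (task$shape[k] == "triangle")) +
      b["beta6"] * (task$outcome[k] == "circle")
  }
  pred
}

# closed-form log marginal likelihood of iid normal data with known variance
# s2 and a normal prior N(m0, v0) on the mean
oracle_conjugate_logml <- function(y, s2, m0, v0) {
  n <- length(y)
  Sigma <- diag(s2, n) + matrix(v0, n, n)
  q <- y - m0
  -n / 2 * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
    0.5 * drop(q %*% solve(Sigma, q))
}
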