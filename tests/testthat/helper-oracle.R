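## Independent reference implementation of the model equations, hand-coded
## term by term and kept deliberately separate in structure from the
## package's compiled right-hand side.  Used as the oracle in the
## derivative-equivalence tests.

oracle_hif1 <- function(o2, p) {
  h <- p$hif
  h$m1 * exp(h$b1 * (1 - abs(h$p1 - o2) / h$t1))
}

oracle_hif2 <- function(o2, p) {
  h <- p$hif
  h$m2 * exp(h$b2 * (1 - abs(h$p2 - o2) / h$t2))
}

oracle_deg <- function(o2, p) {
  if (o2 > p$ros$o2_th)
    exp(p$ros$n_deg * (o2 - p$ros$o2_th) / p$ros$o2_th)
  else 1
}

## state s is a named list/vector with the 13 species; returns named rates
oracle_rhs <- function(s, o2, p) {
  k <- p$kinetics
  H1 <- oracle_hif1(o2, p); H2 <- oracle_hif2(o2, p)
  DEG <- oracle_deg(o2, p)
  s <- as.list(s)
  H1M <- s$hif1a_myc; H2M <- s$hif2a_myc; Myc <- s$myc; cycE <- s$cycE
  E2F <- s$e2f; cycD <- s$cycD; pp <- s$pp; cycD_pp <- s$cycD_pp
  cycE_pp <- s$cycE_pp; Rb <- s$rb; E2F_Rb <- s$e2f_rb; RbP <- s$rbP
  Rb_nP <- s$rb_nP
  n <- k$n
  cycDtot <- cycD + cycD_pp
  k14 <- if (isTRUE(p$unify_k_e2f_rbp)) k$k_E2F_RbP else k$k_cycE_RbP

  d <- list()
  d$hif1a_myc <- -k$kr3A * H1M + k$kf3A * H1 * Myc - k$d_H1M * H1M * DEG
  d$hif2a_myc <- -k$kr3B * H2M + k$kf3B * H2 * Myc - k$d_H2M * H2M * DEG
  d$myc <- k$g_Myc + k$kr3A * H1M - k$kf3A * H1 * Myc +
    k$kr3B * H2M - k$kf3B * H2 * Myc - k$d_Myc * Myc * DEG
  d$cycE <- k$kr12 * cycE_pp - k$kf12 * cycE * pp +
    k$m9 * E2F / (E2F + k$k9) - k$d_cycE * cycE * DEG
  d$e2f <- k$m13 * (Myc / (Myc + k$k13)) * (E2F / (E2F + k$kp13)) +
    k$m_E2F * Myc / (Myc + k$k_E2F) +
    k$m13 * k$eps * (H2M / (H2M + k$k13)) * (E2F / (E2F + k$kp13)) +
    k$m_E2F * H2M / (H2M + k$k_E2F) +
    k$m_E2F_RbP * E2F_Rb * cycDtot / (E2F_Rb + k$k_E2F_RbP) -
    k$k8 * Rb * E2F - k$d_E2F * E2F * DEG
  d$cycD <- k$g_cycD * (1 - H1 / (H1 + k$k3a)) -
    k$kf6B * pp * cycD + k$kr6B * cycD_pp +
    k$m_5cycD * k$eps * H2M / (H2M + k$k_5cycD) +
    k$m_5cycD * Myc / (Myc + k$k_5cycD) - k$d_cycD * cycD * DEG
  d$pp <- k$g_pp * (1 - k$k4 * Myc) -
    k$kf6B * pp * cycD + k$kr6B * cycD_pp -
    k$kf12 * pp * cycE + k$kr12 * cycE_pp - k$d_pp * pp * DEG
  d$cycD_pp <- k$kf6B * pp * cycD - k$kr6B * cycD_pp -
    k$d_cycD_pp * cycD_pp * DEG
  d$cycE_pp <- k$kf12 * pp * cycE - k$kr12 * cycE_pp -
    k$d_cycE_pp * cycE_pp * DEG
  d$rb <- k$g_Rb -
    k$m_cycD_Rb * cycDtot * Rb / (Rb + k$k_cycD_Rb) +
    k$m_RbP * RbP / (RbP + k$k_RbP) -
    k$k8 * Rb * E2F - k$d_Rb * Rb * DEG
  d$e2f_rb <- k$k8 * Rb * E2F -
    k$m_E2F_RbP * E2F_Rb * cycDtot / (E2F_Rb + k$k_E2F_RbP) -
    k$d_E2F_Rb * E2F_Rb * DEG
  d$rbP <- k$m_cycD_Rb * cycDtot * Rb / (Rb + k$k_cycD_Rb) -
    k$m_cycE_RbP * cycE * RbP^(n - 1) / (RbP^(n - 1) + k$k_cycE_RbP) -
    k$m_RbP * RbP / (RbP + k$k_RbP) +
    k$m_E2F_RbP * E2F_Rb * cycDtot / (E2F_Rb + k14) +
    k$m_Rb_nP * Rb_nP^(n - 1) / (Rb_nP^(n - 1) + k$k_Rb_nP) -
    k$d_RbP * RbP * DEG
  d$rb_nP <- k$m_cycE_RbP * cycE * RbP^(n - 1) /
      (RbP^(n - 1) + k$k_cycE_RbP) -
    k$m_Rb_nP * Rb_nP^(n - 1) / (Rb_nP^(n - 1) + k$k_Rb_nP)
  unlist(d)
}

## deterministic pseudo-random positive state for parameterised tests
random_state <- function(seed) {
  set.seed(seed)
  s <- stats::runif(13, 0.01, 3)
  names(s) <- c("hif1a_myc", "hif2a_myc", "myc", "cycE", "e2f", "cycD",
                "pp", "cycD_pp", "cycE_pp", "rb", "e2f_rb", "rbP", "rb_nP")
  s
}

## small perturbed parameter set (keeps validity, changes every rate)
perturbed_params <- function(seed, p = cc_parameters()) {
  set.seed(seed)
  syms <- c("kf3A", "kr3A", "kf3B", "kr3B", "kf6B", "kr6B", "kf12", "kr12",
            "k8", "m9", "k9", "m13", "k13", "k'13", "m_E2F", "k_E2F",
            "m_E2F-RbP", "k_E2F-RbP", "m_5cycD", "k_5cycD", "m_cycD-Rb",
            "k_cycD-Rb", "m_RbP", "k_RbP", "m_cycE-RbP", "k_cycE-RbP",
            "m_Rb-nP", "k_Rb-nP", "k3a", "k4", "epsilon", "g_Myc",
            "g_cycD", "g_p/p", "g_Rb", "d_Myc", "d_Hif1a-Myc",
            "d_Hif2a-Myc", "d_cycE", "d_E2F", "d_cycD", "d_p/p",
            "d_cycD-p/p", "d_cycE-p/p", "d_Rb", "d_E2F-Rb", "d_RbP",
            "b1", "t1", "b2", "t2", "n_deg")
  fac <- stats::runif(length(syms), 0.5, 1.5)
  vals <- cc_get(p, syms) * fac
  do.call(cc_set, c(list(p), as.list(vals)))
}
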