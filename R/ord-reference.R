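# Pure-R transcription of the ventricular myocyte model right-hand side,
# written independently of the compiled path and kept deliberately close to
# the published equation set.  Used as the equation-level cross-check oracle
# in the test suite; far too slow for pacing.  Returns the derivative vector
# with the currents attached as an attribute.
ord_rhs_reference <- function(state, params = ord_params(), t = 0,
                              stim_amp = 0, stim_start = 0, stim_dur = 0) {
  s <- as.list(setNames(as.numeric(state), ord_state_names()))
  epi <- params$cell_type == "epi"
  mid <- params$cell_type == "mid"

  nao <- 140; cao <- 1.8; ko <- 5.4
  R <- 8314; T <- 310; F <- 96485

  L <- 0.01; rad <- 0.0011
  vcell <- 1000 * 3.14 * rad^2 * L
  Ageo <- 2 * 3.14 * rad^2 + 2 * 3.14 * rad * L
  Acap <- 2 * Ageo
  vmyo <- 0.68 * vcell; vnsr <- 0.0552 * vcell
  vjsr <- 0.0048 * vcell; vss <- 0.02 * vcell

  v <- s$v
  ENa <- (R * T / F) * log(nao / s$nai)
  EK <- (R * T / F) * log(ko / s$ki)
  EKs <- (R * T / F) * log((ko + 0.01833 * nao) / (s$ki + 0.01833 * s$nai))
  vw <- if (abs(v) < 1e-6) 1e-6 else v
  vfrt <- vw * F / (R * T)
  vffrt <- vw * F^2 / (R * T)

  d <- setNames(numeric(45), ord_state_names())

  # CaMK
  KmCaMK <- 0.15
  CaMKb <- 0.05 * (1 - s$CaMKt) / (1 + 0.0015 / s$cass)
  CaMKa <- CaMKb + s$CaMKt
  d["CaMKt"] <- 0.05 * CaMKb * (CaMKb + s$CaMKt) - 0.00068 * s$CaMKt
  f_camk <- 1 / (1 + KmCaMK / CaMKa)   # shared phosphorylated fraction

  # fast sodium current
  mss <- 1 / (1 + exp(-(v + 39.57) / 9.871))
  tm <- 1 / (6.765 * exp((v + 11.64) / 34.77) +
               8.552 * exp(-(v + 77.42) / 5.955))
  d["m"] <- (mss - s$m) / tm
  hss <- 1 / (1 + exp((v + 82.90) / 6.086))
  thf <- 1 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                6.149 * exp((v + 0.5096) / 20.27))
  ths <- 1 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                0.3343 * exp((v + 5.730) / 56.66))
  d["hf"] <- (hss - s$hf) / thf
  d["hs"] <- (hss - s$hs) / ths
  h <- 0.99 * s$hf + 0.01 * s$hs
  tj <- 2.038 + 1 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                       0.3052 * exp((v + 0.9941) / 38.45))
  d["j"] <- (hss - s$j) / tj
  hssp <- 1 / (1 + exp((v + 89.1) / 6.086))
  d["hsp"] <- (hssp - s$hsp) / (3 * ths)
  hp <- 0.99 * s$hf + 0.01 * s$hsp
  d["jp"] <- (hss - s$jp) / (1.46 * tj)
  INa <- 75 * (v - ENa) * s$m^3 *
    ((1 - f_camk) * h * s$j + f_camk * hp * s$jp)

  # late sodium current
  mLss <- 1 / (1 + exp(-(v + 42.85) / 5.264))
  d["mL"] <- (mLss - s$mL) / tm
  hLss <- 1 / (1 + exp((v + 87.61) / 7.488))
  d["hL"] <- (hLss - s$hL) / 200
  hLssp <- 1 / (1 + exp((v + 93.81) / 7.488))
  d["hLp"] <- (hLssp - s$hLp) / 600
  GNaL <- 0.0075 * 2.661 * (if (epi) 0.6 else 1)
  INaL <- GNaL * (v - ENa) * s$mL * ((1 - f_camk) * s$hL + f_camk * s$hLp)

  # transient outward current
  ass <- 1 / (1 + exp(-(v - 14.34) / 14.82))
  ta <- 1.0515 / (1 / (1.2089 * (1 + exp(-(v - 18.4099) / 29.3814))) +
                    3.5 / (1 + exp((v + 100) / 29.3814)))
  d["a"] <- (ass - s$a) / ta
  iss <- 1 / (1 + exp((v + 43.94) / 5.711))
  delta_epi <- if (epi) 1 - 0.95 / (1 + exp((v + 70) / 5)) else 1
  tiF <- (4.562 + 1 / (0.3933 * exp(-(v + 100) / 100) +
                         0.08004 * exp((v + 50) / 16.59))) * delta_epi
  tiS <- (23.62 + 1 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                         1.780e-8 * exp((v + 114.1) / 8.079))) * delta_epi
  AiF <- 1 / (1 + exp((v - 213.6) / 151.2))
  d["iF"] <- (iss - s$iF) / tiF
  d["iS"] <- (iss - s$iS) / tiS
  i_gate <- AiF * s$iF + (1 - AiF) * s$iS
  assp <- 1 / (1 + exp(-(v - 24.34) / 14.82))
  d["ap"] <- (assp - s$ap) / ta
  dti_dev <- 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) +
                               exp(-(v - 12.23) / 0.2154))
  dti_rec <- 1 - 0.5 / (1 + exp((v + 70) / 20))
  d["iFp"] <- (iss - s$iFp) / (dti_dev * dti_rec * tiF)
  d["iSp"] <- (iss - s$iSp) / (dti_dev * dti_rec * tiS)
  ip <- AiF * s$iFp + (1 - AiF) * s$iSp
  Gto <- 0.02 * (if (epi || mid) 4 else 1)
  Ito <- Gto * (v - EK) * ((1 - f_camk) * s$a * i_gate + f_camk * s$ap * ip)

  # L-type calcium current
  dss <- 1 / (1 + exp(-(v + 3.940) / 4.230))
  td <- 0.6 + 1 / (exp(-0.05 * (v + 6)) + exp(0.09 * (v + 14)))
  d["d"] <- (dss - s$d) / td
  fss <- 1 / (1 + exp((v + 19.58) / 3.696))
  tff <- 7 + 1 / (0.0045 * exp(-(v + 20) / 10) + 0.0045 * exp((v + 20) / 10))
  tfs <- 1000 + 1 / (3.5e-5 * exp(-(v + 5) / 4) + 3.5e-5 * exp((v + 5) / 6))
  d["ff"] <- (fss - s$ff) / tff
  d["fs"] <- (fss - s$fs) / tfs
  f <- 0.6 * s$ff + 0.4 * s$fs
  tfcaf <- 7 + 1 / (0.04 * exp(-(v - 4) / 7) + 0.04 * exp((v - 4) / 7))
  tfcas <- 100 + 1 / (0.00012 * exp(-v / 3) + 0.00012 * exp(v / 7))
  Afcaf <- 0.3 + 0.6 / (1 + exp((v - 10) / 10))
  d["fcaf"] <- (fss - s$fcaf) / tfcaf
  d["fcas"] <- (fss - s$fcas) / tfcas
  fca <- Afcaf * s$fcaf + (1 - Afcaf) * s$fcas
  d["jca"] <- (fss - s$jca) / 75
  d["ffp"] <- (fss - s$ffp) / (2.5 * tff)
  fp <- 0.6 * s$ffp + 0.4 * s$fs
  d["fcafp"] <- (fss - s$fcafp) / (2.5 * tfcaf)
  fcap <- Afcaf * s$fcafp + (1 - Afcaf) * s$fcas
  km2n <- s$jca
  anca <- 1 / (1000 / km2n + (1 + 0.002 / s$cass)^4)
  d["nca"] <- anca * 1000 - s$nca * km2n
  PhiCaL <- 4 * vffrt * (s$cass * exp(2 * vfrt) - 0.341 * cao) /
    (exp(2 * vfrt) - 1)
  PhiCaNa <- vffrt * (0.75 * s$nass * exp(vfrt) - 0.75 * nao) /
    (exp(vfrt) - 1)
  PhiCaK <- vffrt * (0.75 * s$kss * exp(vfrt) - 0.75 * ko) / (exp(vfrt) - 1)
  PCa <- 0.0001 * 1.007 * (if (epi) 1.2 else if (mid) 2.5 else 1)
  gate_np <- f * (1 - s$nca) + s$jca * fca * s$nca
  gate_p <- fp * (1 - s$nca) + s$jca * fcap * s$nca
  ICaL <- (1 - f_camk) * PCa * PhiCaL * s$d * gate_np +
    f_camk * 1.1 * PCa * PhiCaL * s$d * gate_p
  ICaNa <- (1 - f_camk) * 0.00125 * PCa * PhiCaNa * s$d * gate_np +
    f_camk * 0.00125 * 1.1 * PCa * PhiCaNa * s$d * gate_p
  ICaK <- (1 - f_camk) * 3.574e-4 * PCa * PhiCaK * s$d * gate_np +
    f_camk * 3.574e-4 * 1.1 * PCa * PhiCaK * s$d * gate_p

  # rapid delayed rectifier: hERG Markov scheme (drug-free)
  hp6 <- list(
    a11 = c(0.0007868, 1.535e-8, 4.942), a21 = c(5.455e-6, -0.1688, 4.156),
    a31 = c(0.005509, 7.771e-9, 4.22),   a41 = c(0.001416, -0.02877, 1.459),
    a1 = c(0.0264, 4.631e-5, 4.843),     a2 = c(4.986e-6, -0.004226, 4.23),
    a3 = c(0.001214, 0.008516, 4.962),   a4 = c(1.854e-5, -0.04641, 3.769),
    a51 = c(0.4492, 0.008595, 5.0),      a61 = c(0.01241, 0.1725, 5.568),
    a52 = c(0.3181, 3.613e-8, 4.663),    a62 = c(0.3226, -6.575e-4, 5.0),
    a53 = c(0.149, 0.004668, 2.412),     a63 = c(0.008978, -0.02215, 5.682)
  )
  rate <- function(p) p[1] * exp(p[2] * v) * p[3]^((37 - 20) / 10)
  r <- lapply(hp6, rate)
  d["IC1"] <- -(r$a1 * s$IC1 - r$a2 * s$IC2) +
    (r$a51 * s$C1 - r$a61 * s$IC1)
  d["IC2"] <- (r$a1 * s$IC1 - r$a2 * s$IC2) -
    (r$a3 * s$IC2 - r$a4 * s$IO) + (r$a52 * s$C2 - r$a62 * s$IC2)
  d["C1"] <- -(r$a11 * s$C1 - r$a21 * s$C2) -
    (r$a51 * s$C1 - r$a61 * s$IC1)
  d["C2"] <- (r$a11 * s$C1 - r$a21 * s$C2) -
    (r$a31 * s$C2 - r$a41 * s$O) - (r$a52 * s$C2 - r$a62 * s$IC2)
  d["O"] <- (r$a31 * s$C2 - r$a41 * s$O) - (r$a53 * s$O - r$a63 * s$IO)
  d["IO"] <- (r$a3 * s$IC2 - r$a4 * s$IO) + (r$a53 * s$O - r$a63 * s$IO)
  GKr <- 4.65854545454545618e-2 * (if (epi) 1.3 else if (mid) 0.8 else 1)
  IKr <- GKr * sqrt(ko / 5.4) * s$O * (v - EK)

  # slow delayed rectifier (carries the block hook)
  xs1ss <- 1 / (1 + exp(-(v + 11.60) / 8.932))
  txs1 <- 817.3 + 1 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                         0.001292 * exp(-(v + 210) / 230))
  d["xs1"] <- (xs1ss - s$xs1) / txs1
  txs2 <- 1 / (0.01 * exp((v - 50) / 20) + 0.0193 * exp(-(v + 66.54) / 31))
  d["xs2"] <- (xs1ss - s$xs2) / txs2
  KsCa <- 1 + 0.6 / (1 + (3.8e-5 / s$cai)^1.4)
  GKs <- 0.0034 * 1.87 * (if (epi) 1.4 else 1)
  IKs <- params$iks_scale * GKs * KsCa * s$xs1 * s$xs2 * (v - EKs)

  # inward rectifier
  xk1ss <- 1 / (1 + exp(-(v + 2.5538 * ko + 144.59) /
                          (1.5692 * ko + 3.8115)))
  txk1 <- 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33))
  d["xk1"] <- (xk1ss - s$xk1) / txk1
  rk1 <- 1 / (1 + exp((v + 105.8 - 2.6 * ko) / 9.493))
  GK1 <- 0.1908 * 1.698 * (if (epi) 1.2 else if (mid) 1.3 else 1)
  IK1 <- GK1 * sqrt(ko) * rk1 * s$xk1 * (v - EK)

  # sodium-calcium exchange
  ncx <- function(na_i, ca_i) {
    kna1 <- 15; kna2 <- 5; kna3 <- 88.12; kasymm <- 12.5
    wna <- 6e4; wca <- 6e4; wnaca <- 5e3
    kcaon <- 1.5e6; kcaoff <- 5e3
    hca <- exp(0.167 * v * F / (R * T))
    hna <- exp(0.5224 * v * F / (R * T))
    h1 <- 1 + na_i / kna3 * (1 + hna)
    h2 <- (na_i * hna) / (kna3 * h1)
    h3 <- 1 / h1
    h4 <- 1 + na_i / kna1 * (1 + na_i / kna2)
    h5 <- na_i^2 / (h4 * kna1 * kna2)
    h6 <- 1 / h4
    h7 <- 1 + nao / kna3 * (1 + 1 / hna)
    h8 <- nao / (kna3 * hna * h7)
    h9 <- 1 / h7
    h10 <- kasymm + 1 + nao / kna1 * (1 + nao / kna2)
    h11 <- nao^2 / (h10 * kna1 * kna2)
    h12 <- 1 / h10
    k1 <- h12 * cao * kcaon; k2 <- kcaoff
    k3p <- h9 * wca; k3pp <- h8 * wnaca; k3 <- k3p + k3pp
    k4p <- h3 * wca / hca; k4pp <- h2 * wnaca; k4 <- k4p + k4pp
    k5 <- kcaoff; k6 <- h6 * ca_i * kcaon
    k7 <- h5 * h2 * wna; k8 <- h8 * h11 * wna
    x1 <- k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3)
    x2 <- k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8)
    x3 <- k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3)
    x4 <- k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8)
    E <- c(x1, x2, x3, x4) / (x1 + x2 + x3 + x4)
    allo <- 1 / (1 + (150e-6 / ca_i)^2)
    JncxNa <- 3 * (E[4] * k7 - E[1] * k8) + E[3] * k4pp - E[2] * k3pp
    JncxCa <- E[2] * k2 - E[1] * k1
    allo * (JncxNa + 2 * JncxCa)
  }
  Gncx <- 0.0008 * (if (epi) 1.1 else if (mid) 1.4 else 1)
  INaCa_i <- 0.8 * Gncx * ncx(s$nai, s$cai)
  INaCa_ss <- 0.2 * Gncx * ncx(s$nass, s$cass)

  # sodium-potassium pump
  INaK <- local({
    k1p <- 949.5; k1m <- 182.4; k2p <- 687.2; k2m <- 39.4
    k3p <- 1899; k3m <- 79300; k4p <- 639; k4m <- 40
    Knai <- 9.073 * exp(-0.155 * v * F / (3 * R * T))
    Knao <- 27.78 * exp((1 + 0.155) * v * F / (3 * R * T))
    Kki <- 0.5; Kko <- 0.3582; MgADP <- 0.05; MgATP <- 9.8
    Kmgatp <- 1.698e-7; H <- 1e-7; eP <- 4.2; Khp <- 1.698e-7
    P <- eP / (1 + H / Khp + s$nai / 224 + s$ki / 292)
    a1 <- (k1p * (s$nai / Knai)^3) /
      ((1 + s$nai / Knai)^3 + (1 + s$ki / Kki)^2 - 1)
    b1 <- k1m * MgADP
    a2 <- k2p
    b2 <- (k2m * (nao / Knao)^3) /
      ((1 + nao / Knao)^3 + (1 + ko / Kko)^2 - 1)
    a3 <- (k3p * (ko / Kko)^2) /
      ((1 + nao / Knao)^3 + (1 + ko / Kko)^2 - 1)
    b3 <- (k3m * P * H) / (1 + MgATP / Kmgatp)
    a4 <- (k4p * MgATP / Kmgatp) / (1 + MgATP / Kmgatp)
    b4 <- (k4m * (s$ki / Kki)^2) /
      ((1 + nao / Knao)^3 + (1 + s$ki / Kki)^2 - 1)
    x1 <- a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2
    x2 <- b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4
    x3 <- a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1
    x4 <- b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1
    E <- c(x1, x2, x3, x4) / (x1 + x2 + x3 + x4)
    Pnak <- 30 * (if (epi) 0.9 else if (mid) 0.7 else 1)
    Pnak * (3 * (E[1] * a3 - E[2] * b3) + 2 * (E[4] * b1 - E[3] * a1))
  })

  # background / sarcolemmal pump currents
  xkb <- 1 / (1 + exp(-(v - 14.48) / 18.34))
  IKb <- 0.003 * (if (epi) 0.6 else 1) * xkb * (v - EK)
  INab <- 3.75e-10 * vffrt * (s$nai * exp(vfrt) - nao) / (exp(vfrt) - 1)
  ICab <- 2.5e-8 * 4 * vffrt * (s$cai * exp(2 * vfrt) - 0.341 * cao) /
    (exp(2 * vfrt) - 1)
  IpCa <- 0.0005 * s$cai / (0.0005 + s$cai)

  Istim <- if (t >= stim_start && t < stim_start + stim_dur) stim_amp else 0
  d["v"] <- -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim)

  # fluxes and concentrations
  JdiffNa <- (s$nass - s$nai) / 2
  JdiffK <- (s$kss - s$ki) / 2
  Jdiff <- (s$cass - s$cai) / 0.2
  bt <- 4.75
  rel_inf <- 0.5 * bt * (-ICaL) / (1 + (1.5 / s$cajsr)^8) *
    (if (mid) 1.7 else 1)
  d["Jrelnp"] <- (rel_inf - s$Jrelnp) /
    max(bt / (1 + 0.0123 / s$cajsr), 0.001)
  btp <- 1.25 * bt
  rel_infp <- 0.5 * btp * (-ICaL) / (1 + (1.5 / s$cajsr)^8) *
    (if (mid) 1.7 else 1)
  d["Jrelp"] <- (rel_infp - s$Jrelp) /
    max(btp / (1 + 0.0123 / s$cajsr), 0.001)
  Jrel <- (1 - f_camk) * s$Jrelnp + f_camk * s$Jrelp
  Jupnp <- 0.004375 * s$cai / (s$cai + 0.00092) * (if (epi) 1.3 else 1)
  Jupp <- 2.75 * 0.004375 * s$cai / (s$cai + 0.00092 - 0.00017) *
    (if (epi) 1.3 else 1)
  Jleak <- 0.0039375 * s$cansr / 15
  Jup <- (1 - f_camk) * Jupnp + f_camk * Jupp - Jleak
  Jtr <- (s$cansr - s$cajsr) / 100

  d["nai"] <- -(INa + INaL + 3 * INaCa_i + 3 * INaK + INab) *
    Acap / (F * vmyo) + JdiffNa * vss / vmyo
  d["nass"] <- -(ICaNa + 3 * INaCa_ss) * Acap / (F * vss) - JdiffNa
  d["ki"] <- -(Ito + IKr + IKs + IK1 + IKb + Istim - 2 * INaK) *
    Acap / (F * vmyo) + JdiffK * vss / vmyo
  d["kss"] <- -ICaK * Acap / (F * vss) - JdiffK
  cmdnmax <- 0.05 * (if (epi) 1.3 else 1)
  Bcai <- 1 / (1 + cmdnmax * 0.00238 / (0.00238 + s$cai)^2 +
                 0.07 * 0.0005 / (0.0005 + s$cai)^2)
  d["cai"] <- Bcai * (-(IpCa + ICab - 2 * INaCa_i) * Acap / (2 * F * vmyo) -
                        Jup * vnsr / vmyo + Jdiff * vss / vmyo)
  Bcass <- 1 / (1 + 0.047 * 0.00087 / (0.00087 + s$cass)^2 +
                  1.124 * 0.0087 / (0.0087 + s$cass)^2)
  d["cass"] <- Bcass * (-(ICaL - 2 * INaCa_ss) * Acap / (2 * F * vss) +
                          Jrel * vjsr / vss - Jdiff)
  d["cansr"] <- Jup - Jtr * vjsr / vnsr
  Bcajsr <- 1 / (1 + 10 * 0.8 / (0.8 + s$cajsr)^2)
  d["cajsr"] <- Bcajsr * (Jtr - Jrel)

  attr(d, "currents") <- c(
    IKs = IKs, IKr = IKr, ICaL = ICaL, INaCa = INaCa_i + INaCa_ss,
    INaK = INaK, Ito = Ito, IK1 = IK1, INa = INa, INaL = INaL,
    Istim = Istim
  )
  d
}
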