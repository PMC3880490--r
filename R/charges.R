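# Gasteiger-Marsili partial equalization of orbital electronegativities
# (PEOE).  Electronegativity chi(q) = a + b q + c q^2 per atom type; at each
# iteration charge flows across every bond from the less to the more
# electronegative atom, scaled by the cation electronegativity of the donor
# and damped by 0.5^k.  Charge is conserved exactly by construction.

peoe_params <- function() {
  # columns: a, b, c (eV); types keyed by element + hybridization
  tab <- rbind(
    "H"    = c(7.17, 6.24, -0.56),
    "C.3"  = c(7.98, 9.18, 1.88),
    "C.2"  = c(8.79, 9.32, 1.51),
    "C.1"  = c(10.39, 9.45, 0.73),
    "N.3"  = c(11.54, 10.82, 1.36),
    "N.2"  = c(12.87, 11.15, 0.85),
    "N.1"  = c(15.68, 11.70, -0.27),
    "O.3"  = c(14.18, 12.92, 1.39),
    "O.2"  = c(17.07, 13.79, 0.47),
    "F"    = c(14.66, 13.85, 2.31),
    "Cl"   = c(11.00, 9.69, 1.35),
    "Br"   = c(10.08, 8.47, 1.16),
    "I"    = c(9.90, 7.96, 0.96),
    "S.3"  = c(10.14, 9.13, 1.38),
    "S.2"  = c(10.14, 9.13, 1.38),
    "P.3"  = c(8.90, 8.24, 0.96))
  colnames(tab) <- c("a", "b", "c")
  tab
}

# crude hybridization from bond orders: any triple (or two doubles) -> sp,
# any double/aromatic -> sp2, else sp3
peoe_type <- function(mol) {
  el <- mol$atoms$element
  n <- nrow(mol$atoms)
  maxord <- rep(1, n)
  ndouble <- rep(0L, n)
  b <- mol$bonds
  ord_num <- ifelse(b$order %in% c("ar", "am"), 1.5, suppressWarnings(as.numeric(b$order)))
  ord_num[is.na(ord_num)] <- 1
  for (k in seq_len(nrow(b))) {
    for (a in c(b$i[k], b$j[k])) {
      maxord[a] <- max(maxord[a], ord_num[k])
      if (ord_num[k] == 2) ndouble[a] <- ndouble[a] + 1L
    }
  }
  hyb <- ifelse(maxord >= 3 | ndouble >= 2, "1", ifelse(maxord > 1, "2", "3"))
  ifelse(el %in% c("H", "F", "Cl", "Br", "I"), el, paste0(el, ".", hyb))
}

gasteiger_charges <- function(mol, n_iter = 8) {
  par <- peoe_params()
  type <- peoe_type(mol)
  missing <- setdiff(unique(type), rownames(par))
  if (length(missing) > 0)
    stop("no PEOE parameters for atom type(s): ", paste(missing, collapse = ", "),
         "; use ensure_charges(method = \"zero\") or supply file charges")
  a <- par[type, "a"]; b <- par[type, "b"]; cc <- par[type, "c"]
  chi_plus <- ifelse(type == "H", 20.02, a + b + cc)  # cation electronegativity
  q <- rep(0, nrow(mol$atoms))
  bi <- mol$bonds$i; bj <- mol$bonds$j
  if (length(bi) == 0) return(q)
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q * q
    damp <- 0.5^k
    dq <- rep(0, length(q))
    for (e in seq_along(bi)) {
      i <- bi[e]; j <- bj[e]
      if (chi[i] == chi[j]) next
      if (chi[j] > chi[i]) {   # electrons flow i -> j
        t <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + t
        dq[j] <- dq[j] - t
      } else {
        t <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + t
        dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  q
}
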