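# Toy molecule templates.
#
# These are coarse, chemically plausible stand-ins for the four API
# archetypes (neutral-aromatic, ionic pair with a monovalent counter-ion,
# small neutral ester, donor-rich amide-alcohol) and three excipient monomer
# archetypes, NOT reparameterizations of any real drug or polymer.  Bond and
# angle reference values are taken from the built geometry so each template
# is a minimum of its own bonded terms.

.kb_heavy <- 1e5   # kJ/mol/nm^2, heavy-heavy bonds
.kb_hyd   <- 5e4   # softer X-H bonds so dt = 2 fs stays stable
.ka       <- 300   # kJ/mol/rad^2

# nonbonded parameter table per toy atom type
.type_params <- list(
  CT = c(sigma = 0.350, epsilon = 0.276),  # aliphatic C
  CA = c(sigma = 0.355, epsilon = 0.293),  # aromatic C
  CO = c(sigma = 0.375, epsilon = 0.439),  # carbonyl C
  HC = c(sigma = 0.250, epsilon = 0.126),  # C-bound H
  HP = c(sigma = 0.100, epsilon = 0.065),  # polar H (O-H, N-H)
  OC = c(sigma = 0.296, epsilon = 0.879),  # carbonyl / carboxylate O
  OS = c(sigma = 0.300, epsilon = 0.712),  # ester / hydroxyl O
  NT = c(sigma = 0.325, epsilon = 0.711),  # amine/amide N
  NA_ = c(sigma = 0.333, epsilon = 0.0116) # sodium counter-ion
)

template_atom <- function(name, element, type, charge, x, y, z,
                          donor = FALSE, acceptor = FALSE) {
  p <- .type_params[[type]]
  data.frame(name = name, element = element, charge = charge,
             sigma = p[["sigma"]], epsilon = p[["epsilon"]],
             mass = element_mass(element), donor = donor,
             acceptor = acceptor, x = x, y = y, z = z)
}

# derive r0/theta0 from the built geometry; angles from all bonded triplets
derive_bonded <- function(atoms, bond_pairs) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  bp <- matrix(bond_pairs, ncol = 2, byrow = TRUE)
  r0 <- sqrt(rowSums((xyz[bp[, 1], , drop = FALSE] -
                      xyz[bp[, 2], , drop = FALSE])^2))
  kb <- ifelse(atoms$element[bp[, 1]] == "H" | atoms$element[bp[, 2]] == "H",
               .kb_hyd, .kb_heavy)
  bonds <- data.frame(i = bp[, 1], j = bp[, 2], r0 = r0, k = kb)
  adj <- bond_adjacency(nrow(atoms), bonds)
  ai <- integer(); aj <- integer(); ak <- integer(); th <- numeric()
  for (j in seq_len(nrow(atoms))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (c_ in seq_len(ncol(cmb))) {
      i <- cmb[1, c_]; k <- cmb[2, c_]
      v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ai <- c(ai, i); aj <- c(aj, j); ak <- c(ak, k)
      th <- c(th, acos(max(-1, min(1, cth))) * 180 / pi)
    }
  }
  list(bonds = bonds,
       angles = data.frame(i = ai, j = aj, k = ak, theta0 = th, ktheta = .ka))
}

make_template <- function(name, resname, atoms, bond_pairs,
                          head = NA_integer_, tail = NA_integer_,
                          net_charge = 0) {
  stopifnot(abs(sum(atoms$charge) - net_charge) < 1e-9)
  bt <- derive_bonded(atoms, bond_pairs)
  a <- atoms
  a$resname <- resname
  a$molid <- 1L
  sys <- suppressWarnings(md_system(
    a[, c("name", "element", "resname", "molid", "charge", "sigma",
          "epsilon", "mass", "donor", "acceptor")],
    bonds = bt$bonds, angles = bt$angles))
  structure(list(name = name, resname = resname, system = sys,
                 positions = as.matrix(atoms[, c("x", "y", "z")]),
                 head = head, tail = tail,
                 molar_mass = sum(atoms$mass)),
            class = "molecule_template")
}

#' @export
print.molecule_template <- function(x, ...) {
  cat(sprintf("<molecule_template> %s (%s): %d atoms, M = %.3f g/mol, %d donor H, %d acceptors\n",
              x$name, x$resname, nrow(x$system$atoms), x$molar_mass,
              sum(x$system$atoms$donor), sum(x$system$atoms$acceptor)))
  invisible(x)
}

#' Toy API molecule templates
#'
#' Four archetypes spanning the chemistry the screening statistics must
#' distinguish:
#' \describe{
#'   \item{`"NPX"`}{neutral aromatic acid (benzene ring + COOH); one donor,
#'     interactions dominated by dispersion.}
#'   \item{`"DLO"`}{ionic pair: a glycinate-like anion (net -1, with an
#'     N-H2 donor group) plus an unbonded Na+ counter-ion in the same
#'     molecule; interactions dominated by electrostatics.}
#'   \item{`"DMF"`}{small neutral methyl ester; acceptors only.}
#'   \item{`"OPZ"`}{donor-rich amide-alcohol; two donors, three acceptors.}
#' }
#'
#' @param which one of `"NPX"`, `"DLO"`, `"DMF"`, `"OPZ"`
#' @return a `molecule_template`
#' @export
api_template <- function(which = c("NPX", "DLO", "DMF", "OPZ")) {
  which <- match.arg(which)
  switch(which, NPX = template_npx(), DLO = template_dlo(),
         DMF = template_dmf(), OPZ = template_opz())
}

template_npx <- function() {
  ring_ang <- (0:5) * pi / 3
  at <- list()
  # C1 carries the carboxyl group, C4 (para) a methyl: the ring + methyl
  # provide the dispersion bulk that dominates a neutral aromatic API
  for (i in 1:6)
    at[[i]] <- template_atom(paste0("C", i), "C", "CA",
                             if (i %in% c(1, 4)) 0.0 else -0.06,
                             0.140 * cos(ring_ang[i]), 0.140 * sin(ring_ang[i]), 0)
  k <- 6L
  for (i in c(2, 3, 5, 6)) {
    k <- k + 1L
    at[[k]] <- template_atom(paste0("H", i), "H", "HC", 0.06,
                             0.249 * cos(ring_ang[i]), 0.249 * sin(ring_ang[i]), 0)
  }
  at[[11]] <- template_atom("C7", "C", "CO", 0.34, 0.290, 0.000, 0)
  at[[12]] <- template_atom("O1", "O", "OC", -0.30, 0.351, 0.106, 0,
                            acceptor = TRUE)
  at[[13]] <- template_atom("O2", "O", "OS", -0.38, 0.357, -0.115, 0,
                            acceptor = TRUE)
  at[[14]] <- template_atom("HO", "H", "HP", 0.34, 0.437, -0.165, 0,
                            donor = TRUE)
  at[[15]] <- template_atom("C8", "C", "CT", -0.18, -0.290, 0.000, 0)
  at[[16]] <- template_atom("H81", "H", "HC", 0.06, -0.330, 0.095, 0.030)
  at[[17]] <- template_atom("H82", "H", "HC", 0.06, -0.330, -0.060, 0.080)
  at[[18]] <- template_atom("H83", "H", "HC", 0.06, -0.330, -0.050, -0.090)
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 2,3, 3,4, 4,5, 5,6, 6,1,
             2,7, 3,8, 5,9, 6,10,
             1,11, 11,12, 11,13, 13,14,
             4,15, 15,16, 15,17, 15,18)
  make_template("NPX", "NPX", atoms, bonds)
}

template_dlo <- function() {
  at <- list(
    template_atom("N",   "N",  "NT", -0.98, 0.000,  0.000, 0, acceptor = TRUE),
    template_atom("HN1", "H",  "HP",  0.36, -0.050, 0.088, 0, donor = TRUE),
    template_atom("HN2", "H",  "HP",  0.36, -0.050, -0.088, 0, donor = TRUE),
    template_atom("C1",  "C",  "CT",  0.06, 0.147,  0.000, 0),
    template_atom("H1A", "H",  "HC",  0.06, 0.183,  0.060, 0.080),
    template_atom("H1B", "H",  "HC",  0.06, 0.183,  0.060, -0.080),
    template_atom("C2",  "C",  "CO",  0.70, 0.260, -0.100, 0),
    template_atom("O1",  "O",  "OC", -0.81, 0.360, -0.030, 0, acceptor = TRUE),
    template_atom("O2",  "O",  "OC", -0.81, 0.290, -0.223, 0, acceptor = TRUE),
    template_atom("NA",  "Na", "NA_", 1.00, 0.560, -0.120, 0))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 1,4, 4,5, 4,6, 4,7, 7,8, 7,9)
  make_template("DLO", "DLO", atoms, bonds)
}

template_dmf <- function() {
  at <- list(
    template_atom("C1",  "C", "CT",  0.08, 0.000,  0.000, 0),
    template_atom("H11", "H", "HC",  0.02, -0.040, 0.100, 0),
    template_atom("H12", "H", "HC",  0.02, -0.040, -0.050, 0.087),
    template_atom("H13", "H", "HC",  0.02, -0.040, -0.050, -0.087),
    template_atom("O1",  "O", "OS", -0.25, 0.141,  0.000, 0, acceptor = TRUE),
    template_atom("C2",  "C", "CO",  0.38, 0.254,  0.075, 0),
    template_atom("O2",  "O", "OC", -0.33, 0.254,  0.197, 0, acceptor = TRUE),
    template_atom("C3",  "C", "CT",  0.00, 0.384, -0.005, 0),
    template_atom("H31", "H", "HC",  0.02, 0.424,  0.095, 0),
    template_atom("H32", "H", "HC",  0.02, 0.424, -0.055, 0.087),
    template_atom("H33", "H", "HC",  0.02, 0.424, -0.055, -0.087))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 1,4, 1,5, 5,6, 6,7, 6,8, 8,9, 8,10, 8,11)
  make_template("DMF", "DMF", atoms, bonds)
}

template_opz <- function() {
  # donor-rich but neutral: two donors and three acceptors on an
  # amide-alcohol core with an ethyl tail supplying the dispersion bulk
  at <- list(
    template_atom("O1",  "O", "OS", -0.30, 0.000,  0.000, 0, acceptor = TRUE),
    template_atom("HO",  "H", "HP",  0.22, -0.060, 0.075, 0, donor = TRUE),
    template_atom("C1",  "C", "CT",  0.11, 0.141,  0.000, 0),
    template_atom("H1A", "H", "HC",  0.04, 0.177,  0.060, 0.080),
    template_atom("H1B", "H", "HC",  0.04, 0.177,  0.060, -0.080),
    template_atom("C2",  "C", "CO",  0.27, 0.251, -0.105, 0),
    template_atom("O2",  "O", "OC", -0.25, 0.306, -0.214, 0, acceptor = TRUE),
    template_atom("N",   "N", "NT", -0.37, 0.373, -0.035, 0, acceptor = TRUE),
    template_atom("HN",  "H", "HP",  0.18, 0.413,  0.058, 0, donor = TRUE),
    template_atom("C3",  "C", "CT", -0.02, 0.508, -0.095, 0),
    template_atom("H31", "H", "HC",  0.04, 0.548, -0.045, 0.085),
    template_atom("H32", "H", "HC",  0.04, 0.548, -0.045, -0.085),
    template_atom("C4",  "C", "CT", -0.18, 0.601, -0.215, 0),
    template_atom("H41", "H", "HC",  0.06, 0.701, -0.185, 0),
    template_atom("H42", "H", "HC",  0.06, 0.641, -0.275, 0.085),
    template_atom("H43", "H", "HC",  0.06, 0.641, -0.285, -0.075))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 3,4, 3,5, 3,6, 6,7, 6,8, 8,9, 8,10, 10,11, 10,12,
             10,13, 13,14, 13,15, 13,16)
  make_template("OPZ", "OPZ", atoms, bonds)
}

#' Toy excipient monomer templates
#'
#' Three monomer archetypes with designated head/tail link carbons:
#' `"ELM"` (acrylic-acid-like: COOH side group, one donor),
#' `"HPP"` (polar ester + hydroxyl, phthalate-like polarity),
#' `"HAS"` (acetate-ester + hydroxyl, acetate-succinate-like).
#'
#' @param which one of `"ELM"`, `"HPP"`, `"HAS"`
#' @return a `molecule_template` with `head`/`tail` set
#' @export
excipient_template <- function(which = c("ELM", "HPP", "HAS")) {
  which <- match.arg(which)
  switch(which, ELM = template_elm(), HPP = template_hpp(),
         HAS = template_has())
}

template_elm <- function() {
  at <- list(
    template_atom("CA",  "C", "CT", -0.12, 0.000,  0.000, 0),
    template_atom("HA1", "H", "HC",  0.06, -0.040, 0.090, 0.040),
    template_atom("HA2", "H", "HC",  0.06, -0.040, -0.090, 0.040),
    template_atom("CB",  "C", "CT", -0.06, 0.153,  0.000, 0),
    template_atom("HB",  "H", "HC",  0.06, 0.190,  0.000, 0.100),
    template_atom("CC",  "C", "CO",  0.52, 0.153, -0.150, 0),
    template_atom("OD",  "O", "OC", -0.44, 0.048, -0.213, 0, acceptor = TRUE),
    template_atom("OE",  "O", "OS", -0.53, 0.263, -0.225, 0, acceptor = TRUE),
    template_atom("HE",  "H", "HP",  0.45, 0.303, -0.312, 0, donor = TRUE))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 1,4, 4,5, 4,6, 6,7, 6,8, 8,9)
  make_template("ELM", "ELM", atoms, bonds, head = 1L, tail = 4L)
}

template_hpp <- function() {
  at <- list(
    template_atom("CA",  "C", "CT", -0.10, 0.000,  0.000, 0),
    template_atom("HA1", "H", "HC",  0.06, -0.040, -0.090, 0.040),
    template_atom("HA2", "H", "HC",  0.06, -0.040, -0.090, -0.040),
    template_atom("CB",  "C", "CT",  0.28, 0.153,  0.000, 0),
    template_atom("HB",  "H", "HC",  0.06, 0.190,  0.050, 0.087),
    template_atom("OG",  "O", "OS", -0.66, 0.153, -0.143, 0, acceptor = TRUE),
    template_atom("HG",  "H", "HP",  0.42, 0.203, -0.225, 0, donor = TRUE),
    template_atom("CC",  "C", "CO",  0.51, 0.000,  0.150, 0),
    template_atom("OC",  "O", "OC", -0.43, -0.110, 0.203, 0, acceptor = TRUE),
    template_atom("OE",  "O", "OS", -0.40, 0.115,  0.217, 0, acceptor = TRUE),
    template_atom("CF",  "C", "CT",  0.11, 0.145,  0.355, 0),
    template_atom("HF1", "H", "HC",  0.03, 0.245,  0.395, 0),
    template_atom("HF2", "H", "HC",  0.03, 0.085,  0.445, 0.050),
    template_atom("HF3", "H", "HC",  0.03, 0.085,  0.405, -0.087))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 1,4, 4,5, 4,6, 6,7, 1,8, 8,9, 8,10, 10,11,
             11,12, 11,13, 11,14)
  make_template("HPP", "HPP", atoms, bonds, head = 1L, tail = 4L)
}

template_has <- function() {
  at <- list(
    template_atom("CA",  "C", "CT",  0.12, 0.000,  0.000, 0),
    template_atom("HA1", "H", "HC",  0.06, -0.040, -0.090, 0.040),
    template_atom("HA2", "H", "HC",  0.06, -0.040, -0.090, -0.040),
    template_atom("CB",  "C", "CT",  0.13, 0.153,  0.000, 0),
    template_atom("HB",  "H", "HC",  0.06, 0.190,  0.060, 0.087),
    template_atom("OE",  "O", "OS", -0.40, 0.153, -0.141, 0, acceptor = TRUE),
    template_atom("CC",  "C", "CO",  0.51, 0.213, -0.261, 0),
    template_atom("OC",  "O", "OC", -0.43, 0.103, -0.314, 0, acceptor = TRUE),
    template_atom("CF",  "C", "CT",  0.04, 0.333, -0.351, 0),
    template_atom("HF1", "H", "HC",  0.03, 0.413, -0.301, 0.050),
    template_atom("HF2", "H", "HC",  0.03, 0.373, -0.441, -0.050),
    template_atom("HF3", "H", "HC",  0.03, 0.293, -0.411, 0.087),
    template_atom("OG",  "O", "OS", -0.66, 0.000,  0.143, 0, acceptor = TRUE),
    template_atom("HG",  "H", "HP",  0.42, 0.050,  0.225, 0, donor = TRUE))
  atoms <- do.call(rbind, at)
  bonds <- c(1,2, 1,3, 1,4, 4,5, 4,6, 6,7, 7,8, 7,9, 9,10, 9,11, 9,12,
             1,13, 13,14)
  make_template("HAS", "HAS", atoms, bonds, head = 1L, tail = 4L)
}
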