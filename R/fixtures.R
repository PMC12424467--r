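# Seeded synthetic-data generator. Produces feature tables with
# controlled statistical structure (score-space clusters, LogIE segments
# spanning both ESI filter regimes, a configurable share of donor-free
# structures) plus ground-truth labels, so every pipeline stage is
# testable without downloading any external deposit. Distributions are
# deliberately simple: the goal is exercising the machinery, not
# mimicking real descriptor marginals.

#' Specification for the synthetic feature-table generator
#'
#' @param n Number of compounds.
#' @param seed Integer seed; the generator never touches the global RNG
#'   state (it is saved and restored).
#' @param n_clusters Number of Gaussian clusters planted in a 3-d latent
#'   space (default 4).
#' @param cluster_spread Within-cluster standard deviation in latent
#'   units (default 1; cluster centres have sd 2).
#' @param logie_range Overall LogIE support `(lo, hi)`, default
#'   `c(-2, 6)` bracketing both decision thresholds.
#' @param class_proportions Mobility-class probabilities (3 values
#'   summing to 1).
#' @param fraction_hbd_zero Fraction of structures forced to zero H-bond
#'   donors (default 0.2), exercising the ESI(-) donor criterion.
#' @param frac_logie_high Fraction of LogIE values drawn above 3.5
#'   (ESI(+)-eligible regime; default 0.3).
#' @param frac_logie_low Fraction drawn below 1.5 (ESI(-) regime;
#'   default 0.3). The remainder falls between the thresholds.
#' @param planted_direction Optional length-11 unit direction for the
#'   continuous block; when set, those columns become
#'   `t * direction * 3 + N(0, cluster_spread)` so PCA recovery of the
#'   planted axis can be tested.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n, seed = 1L, n_clusters = 4L, cluster_spread = 1,
                         logie_range = c(-2, 6),
                         class_proportions = c(1, 1, 1) / 3,
                         fraction_hbd_zero = 0.2,
                         frac_logie_high = 0.3, frac_logie_low = 0.3,
                         planted_direction = NULL) {
  check_that(is_count(n), "validation", "n must be >= 1")
  check_that(length(class_proportions) == 3L &&
               all(class_proportions >= 0) &&
               abs(sum(class_proportions) - 1) < 1e-9, "validation",
             "class_proportions must be 3 non-negative values summing to 1")
  check_that(fraction_hbd_zero >= 0 && fraction_hbd_zero <= 1, "validation",
             "fraction_hbd_zero must be in [0, 1]")
  check_that(frac_logie_high >= 0 && frac_logie_low >= 0 &&
               frac_logie_high + frac_logie_low <= 1, "validation",
             "LogIE segment fractions must be non-negative and sum <= 1")
  check_that(length(logie_range) == 2L && logie_range[1] < 1.5 &&
               logie_range[2] > 3.5, "validation",
             "logie_range must bracket both thresholds (lo < 1.5, hi > 3.5)")
  if (!is.null(planted_direction)) {
    check_that(length(planted_direction) == 11L &&
                 all(is.finite(planted_direction)), "validation",
               "planted_direction must be 11 finite values")
    planted_direction <- planted_direction /
      sqrt(sum(planted_direction^2))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 n_clusters = as.integer(n_clusters),
                 cluster_spread = cluster_spread,
                 logie_range = logie_range,
                 class_proportions = class_proportions,
                 fraction_hbd_zero = fraction_hbd_zero,
                 frac_logie_high = frac_logie_high,
                 frac_logie_low = frac_logie_low,
                 planted_direction = planted_direction),
            class = "fixture_spec")
}

# run fn under a private RNG stream; the caller's state is untouched
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic 13-variable feature table with ground truth
#'
#' Deterministic given the seed. The continuous block carries planted
#' cluster structure in a 3-d latent subspace; `mobility_class` is drawn
#' from the class proportions; `log_ie` is drawn from three uniform
#' segments placing known fractions above 3.5 and below 1.5; a known
#' fraction of rows has `hbd = 0`. Ground-truth labels (cluster id,
#' intended mobility class, intended ESI eligibility per polarity) are
#' emitted alongside, computed from the generator's own draws -- an
#' implementation of the eligibility inequalities independent of
#' [esi_filter()].
#'
#' @param spec A [fixture_spec()].
#' @return List: `features` (data frame `id` + 13 model variables),
#'   `truth` (data frame `id`, `cluster`, `mobility_class`, `elig_pos`,
#'   `elig_neg`), and `spec`.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, function() {
    n <- spec$n
    id <- sprintf("SYN%06d", seq_len(n))

    cluster <- sample.int(spec$n_clusters, n, replace = TRUE)
    centers <- matrix(stats::rnorm(spec$n_clusters * 3, sd = 2),
                      spec$n_clusters, 3)
    latent <- centers[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * 3, sd = spec$cluster_spread), n, 3)

    if (is.null(spec$planted_direction)) {
      # fixed latent->feature weights give correlated continuous columns
      W <- matrix(sin(seq_len(11 * 3)), nrow = 3, ncol = 11)
      cont <- latent %*% W + matrix(stats::rnorm(n * 11, sd = 0.3), n, 11)
    } else {
      t <- latent[, 1]
      cont <- t %*% t(spec$planted_direction) * 3 +
        matrix(stats::rnorm(n * 11, sd = spec$cluster_spread), n, 11)
    }
    # map the first five latent features onto descriptor-like scales
    mw <- 400 + 120 * cont[, 1]; mw <- pmax(mw, 60)
    xlogp <- 2 + 1.5 * cont[, 2]
    tpsa <- pmax(80 + 35 * cont[, 3], 0)
    hbd <- pmax(round(2 + 1.2 * cont[, 4]), 0)
    hba <- pmax(round(4 + 1.5 * cont[, 5]), 0)
    n_zero <- round(spec$fraction_hbd_zero * n)
    if (n_zero > 0L) {
      hbd[sample.int(n, n_zero)] <- 0
    } else {
      hbd <- pmax(hbd, 1)  # keep the donor criterion non-trivial
    }
    emds <- matrix(stats::runif(n * 6, -0.5, 0.5), n, 6)

    mobility <- sample.int(3L, n, replace = TRUE,
                           prob = spec$class_proportions)
    seg <- sample(c("high", "mid", "low"), n, replace = TRUE,
                  prob = c(spec$frac_logie_high,
                           1 - spec$frac_logie_high - spec$frac_logie_low,
                           spec$frac_logie_low))
    log_ie <- numeric(n)
    log_ie[seg == "high"] <- stats::runif(sum(seg == "high"), 3.5,
                                          spec$logie_range[2])
    log_ie[seg == "mid"] <- stats::runif(sum(seg == "mid"), 1.5, 3.5)
    log_ie[seg == "low"] <- stats::runif(sum(seg == "low"),
                                         spec$logie_range[1], 1.5)

    features <- data.frame(id = id, mw = mw, xlogp = xlogp, tpsa = tpsa,
                           hbd = hbd, hba = hba,
                           emd_CH2 = emds[, 1], emd_CO = emds[, 2],
                           emd_CCl = emds[, 3], emd_CN = emds[, 4],
                           emd_CF2 = emds[, 5], emd_CS = emds[, 6],
                           mobility_class = as.numeric(mobility),
                           log_ie = log_ie, stringsAsFactors = FALSE)
    truth <- data.frame(id = id, cluster = cluster,
                        mobility_class = mobility,
                        elig_pos = seg == "high",
                        elig_neg = seg == "low" & hbd > 0,
                        stringsAsFactors = FALSE)
    list(features = features, truth = truth, spec = spec)
  })
}

# Embedded library of common, documented, valid SMILES spanning solvents,
# drugs, PFAS-like acids and sugars; covers hbd = 0 and hbd > 0,
# halogenated and non-halogenated structures.
.smiles_library <- data.frame(
  name = c("water", "methanol", "ethanol", "acetone", "acetonitrile",
           "dmso", "hexane", "heptane", "octanol", "benzene", "toluene",
           "naphthalene", "thf", "dioxane", "chloroform",
           "dichloromethane", "phenol", "aniline", "pyridine",
           "imidazole", "nitrobenzene", "benzoic_acid", "methyl_benzoate",
           "urea", "glycerol", "glucose", "citric_acid", "caffeine",
           "paracetamol", "ibuprofen", "aspirin", "metformin", "atrazine",
           "carbamazepine", "diclofenac", "sulfamethoxazole", "deet",
           "bisphenol_a", "triclosan", "tfa", "pfoa", "pfbs",
           "caprolactam", "taurine", "benzamide"),
  smiles = c("O", "CO", "CCO", "CC(C)=O", "CC#N", "CS(C)=O", "CCCCCC",
             "CCCCCCC", "CCCCCCCCO", "c1ccccc1", "Cc1ccccc1",
             "c1ccc2ccccc2c1", "C1CCOC1", "C1COCCO1", "ClC(Cl)Cl",
             "ClCCl", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1", "c1c[nH]cn1",
             "O=[N+]([O-])c1ccccc1", "OC(=O)c1ccccc1",
             "COC(=O)c1ccccc1", "NC(N)=O", "OCC(O)CO",
             "OCC1OC(O)C(O)C(O)C1O", "OC(=O)CC(O)(CC(O)=O)C(O)=O",
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(=O)Nc1ccc(O)cc1",
             "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
             "CN(C)C(=N)NC(=N)N", "CCNc1nc(Cl)nc(NC(C)C)n1",
             "NC(=O)N1c2ccccc2C=Cc2ccccc21",
             "OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl",
             "Cc1cc(no1)NS(=O)(=O)c1ccc(N)cc1",
             "CCN(CC)C(=O)c1cccc(C)c1",
             "CC(C)(c1ccc(O)cc1)c1ccc(O)cc1",
             "Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl", "OC(=O)C(F)(F)F",
             "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
             "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F", "O=C1CCCCCN1",
             "NCCS(O)(=O)=O", "NC(=O)c1ccccc1"),
  stringsAsFactors = FALSE
)

#' Embedded set of documented, valid SMILES
#'
#' Returns compound records drawn from a small embedded library of
#' common structures (solvents, drugs, perfluorinated acids, sugars)
#' covering donor-free and donor-bearing, halogenated and
#' non-halogenated chemistry.
#'
#' @param size Number of records (0 to the library size, in library
#'   order).
#' @return List of `compound_record`s (`size = 0` gives an empty list).
#' @export
generate_smiles_set <- function(size = nrow(.smiles_library)) {
  check_that(is.numeric(size) && length(size) == 1L && size >= 0 &&
               size == floor(size), "validation",
             "size must be a non-negative integer")
  check_that(size <= nrow(.smiles_library), "validation",
             sprintf("size %d exceeds the embedded library (%d entries)",
                     size, nrow(.smiles_library)))
  if (size == 0L) return(list())
  lapply(seq_len(size), function(i) {
    compound_record(.smiles_library$name[i], .smiles_library$smiles[i])
  })
}
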