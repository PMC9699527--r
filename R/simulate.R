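# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments and seed: identical calls give identical outputs, and a
# global seed fans out to per-component child seeds by fixed offsets so
# adding a generator never perturbs existing streams.

#' Derive a per-component child seed from one global seed
#'
#' @param seed global integer seed.
#' @param component one of `"chemicals"`, `"toxicity"`, `"dose_response"`,
#'   `"binary"`.
#' @return Integer child seed (kept below 2^31).
#' @export
child_seed <- function(seed, component = c("chemicals", "toxicity",
                                           "dose_response", "binary")) {
  component <- match.arg(component)
  offset <- c(chemicals = 101L, toxicity = 211L,
              dose_response = 307L, binary = 401L)[[component]]
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Simulate a chemical table with a dominant top-k
#'
#' Draws log-normal air concentrations for `n_chemicals` synthetic
#' chemicals and rescales so that the `k_top` most abundant hold exactly
#' `dominance` of the total mass — the composition structure of a
#' creosote/wildfire air sample in which 7 of 30 detected chemicals carry
#' over 97% of the concentration. CAS-like identifiers are synthetic and
#' unique.
#'
#' @param n_chemicals number of detected chemicals (default 30).
#' @param k_top size of the dominant set (default 7).
#' @param dominance exact mass share of the top `k_top` (default 0.97).
#' @param seed integer seed.
#' @return A [chemical_table()] sorted by decreasing concentration.
#' @export
simulate_chemical_table <- function(n_chemicals = 30, k_top = 7,
                                    dominance = 0.97, seed = 1) {
  if (k_top >= n_chemicals) {
    stop("dominance rescaling needs k_top < n_chemicals", call. = FALSE)
  }
  if (dominance <= 0 || dominance >= 1) {
    stop("dominance must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  conc <- sort(rlnorm(n_chemicals, meanlog = log(50), sdlog = 1.5),
               decreasing = TRUE)
  top <- seq_len(k_top)
  total <- sum(conc)
  conc[top] <- conc[top] * (dominance * total / sum(conc[top]))
  conc[-top] <- conc[-top] * ((1 - dominance) * total / sum(conc[-top]))
  i <- seq_len(n_chemicals)
  chemical_table(name = sprintf("sim-pah-%02d", i),
                 cas = sprintf("%04d-%02d-%d", 1000 + i, i %% 100, i %% 10),
                 concentration = conc)
}

# default per-metric-group availability profile (chemicals with >= 1
# non-missing member metric out of 30)
default_missingness_profile <- function() {
  list(`RfD|RfC` = 10L, `OSF|IUR` = 6L, IARC = 18L, RPF = 7L,
       TEF = NA_integer_,  # NA means all chemicals
       BMC = 14L)
}

#' Simulate a toxicity table with realistic structure and missingness
#'
#' Generates chemical-by-metric hazard values over wide log-uniform ranges
#' with a shared latent hazard so that paired metrics (RfC/RfD, and
#' OSF/CPV) are strongly rank-correlated, as regulatory values derived
#' from common studies are; `paired = FALSE` draws every metric
#' independently. Missingness is placed to match the availability profile
#' exactly (counts of chemicals with at least one value per metric group),
#' and present numeric cells are split between `empirical` and
#' `qsar_predicted` provenance.
#'
#' @param chemicals a [chemical_table()] giving the CAS universe.
#' @param profile named list of per-group availability counts, as
#'   `default_missingness_profile()`; `NA` means all chemicals.
#' @param paired couple RfC/RfD and OSF/CPV (and tie IARC to the latent
#'   hazard); default `TRUE`.
#' @param seed integer seed.
#' @return A [toxicity_table()] over `chemicals$cas`.
#' @export
simulate_toxicity_table <- function(chemicals,
                                    profile = default_missingness_profile(),
                                    paired = TRUE, seed = 1) {
  stopifnot(inherits(chemicals, "chemical_table"))
  set.seed(seed)
  n <- nrow(chemicals)
  bad <- vapply(profile, function(x) !is.na(x) && x > n, logical(1))
  if (any(bad)) {
    stop("availability count exceeds number of chemicals for group(s): ",
         paste(names(profile)[bad], collapse = ", "), call. = FALSE)
  }
  # latent hazard scores; shared when paired, independent otherwise
  h_noncancer <- rnorm(n)
  h_cancer <- rnorm(n)
  draw <- function(latent, lo, hi, inverse = FALSE, noise = 0.15) {
    z <- if (paired) latent + rnorm(n, sd = noise) else rnorm(n)
    q <- (rank(z) - 0.5) / n
    v <- 10^(log10(lo) + (if (inverse) 1 - q else q) * (log10(hi) - log10(lo)))
    v
  }
  # lower-is-more-hazardous: high latent hazard -> small value
  values <- data.frame(
    RfC = draw(h_noncancer, 1e-5, 1e-1, inverse = TRUE),
    RfD = draw(h_noncancer, 1e-4, 1e0, inverse = TRUE),
    IUR = draw(h_cancer, 1e-6, 1e-3),
    OSF = draw(h_cancer, 1e-2, 1e1),
    CPV = draw(h_cancer, 1e-2, 1e1),
    RPF = draw(h_cancer, 1e-3, 1e1),
    TEF = draw(h_cancer, 1e-3, 1e0),
    IARC = NA_character_,
    BMC = draw(h_noncancer, 1e-1, 5e1, inverse = TRUE),
    stringsAsFactors = FALSE)
  # IARC: cut the cancer latent into hazard-descending categories when
  # paired; most air-sampled chemicals fall in 2B/3/NC
  lev <- iarc_levels()
  if (paired) {
    q <- (rank(h_cancer) - 0.5) / n  # high q = high latent hazard
    cat_i <- cut(1 - q, breaks = c(0, 0.05, 0.15, 0.45, 0.85, 1),
                 labels = FALSE)
    values$IARC <- lev[cat_i]
  } else {
    values$IARC <- sample(lev, n, replace = TRUE,
                          prob = c(0.05, 0.10, 0.30, 0.40, 0.15))
  }
  # place missingness to match the profile exactly: sampled chemicals keep
  # every member metric of their group, all others lose the whole group
  groups <- list(`RfD|RfC` = c("RfD", "RfC"), `OSF|IUR` = c("OSF", "IUR"),
                 IARC = "IARC", RPF = "RPF", TEF = "TEF", BMC = "BMC")
  for (g in names(groups)) {
    count <- profile[[g]]
    if (is.null(count) || is.na(count)) next  # group fully observed
    keep <- sample.int(n, count)
    for (m in groups[[g]]) {
      values[[m]][setdiff(seq_len(n), keep)] <- NA
    }
  }
  # CPV mirrors OSF availability (it is the CalEPA analogue of OSF)
  values$CPV[is.na(values$OSF)] <- NA
  present <- !is.na(as.matrix(values))
  prov <- ifelse(present, "empirical", "missing")
  numeric_cols <- setdiff(names(values), "IARC")
  for (m in numeric_cols) {
    idx <- which(present[, m])
    if (length(idx) > 1) {
      pred <- sample(idx, floor(length(idx) / 2))
      prov[pred, m] <- "qsar_predicted"
    }
  }
  toxicity_table(chemicals$cas, values,
                 as.data.frame(prov, stringsAsFactors = FALSE))
}

four_pl <- function(conc, lower, upper, ec50, hill) {
  # decreasing for hill > 0 with upper at conc -> 0
  lower + (upper - lower) / (1 + (conc / ec50)^hill)
}

#' Simulate a continuous plate assay from a 4-parameter log-logistic curve
#'
#' Responses are the curve value times multiplicative Gaussian noise at
#' the stated coefficient of variation; vehicle wells sit at the upper
#' asymptote. With `cv = 0` all responses lie exactly on the curve and the
#' vehicle mean equals the upper asymptote.
#'
#' @param lower,upper,ec50,hill true curve parameters (response falls from
#'   `upper` toward `lower` with increasing concentration; `ec50` µM).
#' @param concentrations tested concentrations, µM (> 0).
#' @param replicates wells per concentration per plate (default 6).
#' @param plates number of plates (default 1).
#' @param n_vehicle vehicle wells per plate (default `replicates`).
#' @param cv multiplicative noise coefficient of variation (default 0.1).
#' @param seed integer seed.
#' @return data.frame `plate`, `well`, `concentration`, `signal`,
#'   `is_vehicle` — the schema [percent_control()] expects.
#' @export
simulate_dose_response <- function(lower = 0, upper = 100, ec50 = 50,
                                   hill = 2,
                                   concentrations = c(1, 5, 10, 50, 100,
                                                      500, 1000),
                                   replicates = 6, plates = 1,
                                   n_vehicle = replicates, cv = 0.1,
                                   seed = 1) {
  stopifnot(all(concentrations > 0), replicates >= 1, plates >= 1)
  set.seed(seed)
  out <- list()
  for (p in seq_len(plates)) {
    conc <- c(rep(0, n_vehicle),
              rep(concentrations, each = replicates))
    mu <- ifelse(conc == 0, upper, four_pl(conc, lower, upper, ec50, hill))
    signal <- mu * (1 + if (cv > 0) rnorm(length(mu), sd = cv) else 0)
    out[[p]] <- data.frame(plate = p, well = seq_along(conc),
                           concentration = conc, signal = signal,
                           is_vehicle = conc == 0)
  }
  do.call(rbind, out)
}

#' Simulate binary developmental endpoints as Bernoulli trials
#'
#' Per-animal Bernoulli draws for the thirteen zebrafish endpoints over a
#' concentration series. The `target` endpoint(s) follow a log-logistic
#' incidence curve rising from `background` toward `upper`; all other
#' endpoints stay at the background rate, as do controls (concentration
#' 0). With `latent_rho > 0`, endpoints within an animal share a latent
#' Gaussian severity variable (single-factor threshold model) so that
#' outcomes are positively correlated while marginal incidences are
#' preserved; endpoints are independent by default.
#'
#' @param ec50 incidence-curve midpoint, µM.
#' @param hill incidence-curve steepness.
#' @param concentrations tested concentrations, µM.
#' @param n_per_conc animals per concentration across all plates
#'   (default 36 = 3 plates x 12 wells).
#' @param plates number of replicate plates (default 3).
#' @param n_control control animals per plate (default 12).
#' @param background background incidence in controls and non-target
#'   endpoints (default 0.02).
#' @param upper top of the incidence curve (default 1).
#' @param target endpoint id(s) following the curve (default `"MORT"`).
#' @param latent_rho within-animal endpoint correlation (default 0).
#' @param seed integer seed.
#' @return data.frame `plate`, `well`, `concentration`, `endpoint`,
#'   `outcome` — the schema [incidence()] expects.
#' @export
simulate_binary_endpoints <- function(ec50 = 40, hill = 4,
                                      concentrations = c(5, 10, 20, 40, 80,
                                                         160, 320),
                                      n_per_conc = 36, plates = 3,
                                      n_control = 12, background = 0.02,
                                      upper = 1, target = "MORT",
                                      latent_rho = 0, seed = 1) {
  stopifnot(n_per_conc %% plates == 0, background >= 0, background < 1,
            upper <= 1, latent_rho >= 0, latent_rho < 1)
  endpoints <- zf_endpoint_registry()$endpoint
  if (!all(target %in% endpoints)) {
    stop("target endpoint(s) not in the registry: ",
         paste(setdiff(target, endpoints), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  per_plate <- n_per_conc / plates
  rows <- list(); ri <- 1
  p_curve <- function(conc) {
    if (conc == 0) return(background)
    background + (upper - background) / (1 + (ec50 / conc)^hill)
  }
  for (p in seq_len(plates)) {
    w <- 0
    for (conc in c(0, concentrations)) {
      n_animals <- if (conc == 0) n_control else per_plate
      for (a in seq_len(n_animals)) {
        w <- w + 1
        probs <- ifelse(endpoints %in% target, p_curve(conc), background)
        if (latent_rho > 0) {
          u <- rnorm(1)
          eps <- rnorm(length(endpoints))
          z <- sqrt(latent_rho) * u + sqrt(1 - latent_rho) * eps
          outcome <- as.integer(z < qnorm(probs))
        } else {
          outcome <- rbinom(length(endpoints), 1, probs)
        }
        rows[[ri]] <- data.frame(plate = p, well = w,
                                 concentration = conc,
                                 endpoint = endpoints, outcome = outcome)
        ri <- ri + 1
      }
    }
  }
  do.call(rbind, rows)
}
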