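# Synthetic multi-laboratory study generator with analytic ground truth.
#
# Emulates the statistical structure of a three-laboratory zebrafish embryo
# dose-range-finding screen: hill-shaped mortality and malformation
# dose-response per substance, lab-specific potency shifts (protocol
# effects) and background rates, triplicate plates, 12 embryos per test
# concentration, 12 vehicle-control and 7 positive-control wells per plate.

#' Configure a synthetic screening study
#'
#' Defaults emulate the design of a three-laboratory dose-range-finding
#' screen: three labs with different in-house protocols expressed as pure
#' log10 potency shifts and background-rate differences (one lab more
#' potent overall, one lab with an elevated background malformation rate),
#' a panel of test substances with hill-shaped dose-response, three plates
#' per substance, at least seven log-spaced concentrations up to 100 uM,
#' 12 embryos per test concentration, 12 vehicle and 7 positive-control
#' wells per plate.
#'
#' @param labs data.frame with columns `lab_id`, `potency_shift_log10`
#'   (added to every substance's log10 EC50 at that lab; negative = more
#'   potent), `background_mortality_p`, `background_malformation_p`.
#' @param substances data.frame with columns `substance_id`, `active`,
#'   `log10_ec50_malf`, `log10_ec50_mort`, `hill_slope`, and optional
#'   `duplicate_of` (blind duplicates share true parameters).
#' @param n_concs number of test concentrations (default 7).
#' @param conc_range_uM lowest and highest test concentration, log-spaced
#'   (default 0.1 to 100 uM).
#' @param embryos_per_conc embryos per test concentration (default 12).
#' @param plates_per_substance plates per substance per lab (default 3).
#' @param vehicle_wells,positive_wells control wells per plate (12 and 7).
#' @param weeks number of testing weeks the plates are spread over.
#' @param mort24_frac fraction of the 120-hpf mortality probability already
#'   expressed at 24 hpf (default 0.55, matching the observed 1.4- to
#'   1.9-fold lower potency of the 24-hpf endpoint).
#' @param positive_control list with hill parameters of the positive
#'   control per lab (`log10_ec50` named by lab, `hill_slope`).
#' @param seed root seed for [generate_study()].
#' @return list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(
    labs = default_labs(),
    substances = default_substances(),
    n_concs = 7L,
    conc_range_uM = c(0.1, 100),
    embryos_per_conc = 12L,
    plates_per_substance = 3L,
    vehicle_wells = 12L,
    positive_wells = 7L,
    weeks = 3L,
    mort24_frac = 0.55,
    positive_control = list(
      log10_ec50 = c(LabA = log10(16), LabB = log10(3), LabC = log10(16)),
      hill_slope = 2),
    seed = 1L) {
  need_lab <- c("lab_id", "potency_shift_log10", "background_mortality_p",
                "background_malformation_p")
  if (!all(need_lab %in% names(labs))) {
    .stopf("labs must have columns: %s", paste(need_lab, collapse = ", "))
  }
  need_sub <- c("substance_id", "active", "log10_ec50_malf",
                "log10_ec50_mort", "hill_slope")
  if (!all(need_sub %in% names(substances))) {
    .stopf("substances must have columns: %s", paste(need_sub, collapse = ", "))
  }
  bad <- c(
    if (any(labs$background_mortality_p < 0 | labs$background_mortality_p > 1))
      "background_mortality_p",
    if (any(labs$background_malformation_p < 0 | labs$background_malformation_p > 1))
      "background_malformation_p",
    if (any(substances$active &
            (is.na(substances$hill_slope) | substances$hill_slope <= 0)))
      "hill_slope",
    if (any(substances$active & (is.na(substances$log10_ec50_malf) |
                                 is.na(substances$log10_ec50_mort))))
      "log10_ec50",
    if (n_concs < 2L) "n_concs",
    if (conc_range_uM[1L] <= 0 || conc_range_uM[2L] <= conc_range_uM[1L])
      "conc_range_uM",
    if (embryos_per_conc < 1L) "embryos_per_conc",
    if (mort24_frac < 0 || mort24_frac > 1) "mort24_frac")
  if (length(bad) > 0L) {
    .stopf("invalid synthetic study configuration field(s): %s",
           paste(bad, collapse = ", "))
  }
  structure(list(labs = labs, substances = substances,
                 n_concs = as.integer(n_concs),
                 conc_range_uM = as.numeric(conc_range_uM),
                 embryos_per_conc = as.integer(embryos_per_conc),
                 plates_per_substance = as.integer(plates_per_substance),
                 vehicle_wells = as.integer(vehicle_wells),
                 positive_wells = as.integer(positive_wells),
                 weeks = as.integer(weeks),
                 mort24_frac = mort24_frac,
                 positive_control = positive_control,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Default synthetic laboratory panel
#'
#' Three labs: LabA is half a log10 unit more potent than the reference
#' (its protocol renews exposure media) and has the highest background
#' mortality; LabC has an elevated background malformation rate; LabB is
#' the reference.
#'
#' @return data.frame of lab parameters.
#' @export
default_labs <- function() {
  data.frame(
    lab_id = c("LabA", "LabB", "LabC"),
    potency_shift_log10 = c(-0.5, 0, 0),
    background_mortality_p = c(0.09, 0.03, 0.02),
    background_malformation_p = c(0.01, 0.02, 0.10),
    stringsAsFactors = FALSE)
}

#' Default synthetic substance panel
#'
#' 39 substances (33 active, 6 inactive) with log-uniformly spread
#' malformation EC50s across the tested range, mortality EC50s a factor
#' ~2.5 higher (malformation precedes death), and hill slopes between 1.5
#' and 4. Three of the active substances are blinded duplicates sharing
#' the true parameters of their partners.
#'
#' @param n_active,n_inactive panel composition (default 33 + 6).
#' @param n_duplicated how many active substances also appear as blind
#'   duplicates (default 3).
#' @return data.frame of substance parameters.
#' @export
default_substances <- function(n_active = 33L, n_inactive = 6L,
                               n_duplicated = 3L) {
  ids <- sprintf("S%02d", seq_len(n_active + n_inactive))
  active <- rep(c(TRUE, FALSE), c(n_active, n_inactive))
  # deterministic spread of potencies over the tested range (0.1-100 uM)
  ec50 <- seq(-1.5, 1.6, length.out = n_active)
  slope <- rep(c(1.5, 2, 3, 4), length.out = n_active)
  sub <- data.frame(
    substance_id = ids,
    active = active,
    log10_ec50_malf = c(ec50, rep(NA_real_, n_inactive)),
    log10_ec50_mort = c(ec50 + 0.4, rep(NA_real_, n_inactive)),
    hill_slope = c(slope, rep(NA_real_, n_inactive)),
    duplicate_of = NA_character_,
    stringsAsFactors = FALSE)
  if (n_duplicated > 0L) {
    src <- sub$substance_id[seq_len(n_duplicated)]
    dup <- sub[seq_len(n_duplicated), ]
    dup$substance_id <- paste0(src, "dup")
    dup$duplicate_of <- src
    sub <- rbind(sub, dup)
  }
  rownames(sub) <- NULL
  sub
}

# Hill response probability: background plus (1 - background) times a
# non-decreasing hill term with the lab potency shift applied to the EC50.
.hill_p <- function(conc, p_bg, log10_ec50, slope, shift = 0) {
  ifelse(conc <= 0, p_bg,
         p_bg + (1 - p_bg) / (1 + (10^(log10_ec50 + shift) / conc)^slope))
}

#' Generate a synthetic multi-laboratory screening dataset
#'
#' Draws well-level records under the configured design. Each embryo has
#' one latent uniform that drives both death times through nested
#' thresholds (`dead_24` iff `u < p24`, `dead_120` iff `u < p120`,
#' `p24 <= p120`), so mortality is monotone in time by construction.
#' Survivors are malformed with the malformation hill probability;
#' malformed survivors receive a generic recorded phenotype term per
#' harmonized class drawn for the lab.
#'
#' @param config a [synthetic_study_config()].
#' @return A [study_dataset()] with a vocabulary covering the generated
#'   terms and ground-truth parameters attached as attribute `config`.
#' @export
generate_study <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(config$seed)
  concs <- 10^seq(log10(config$conc_range_uM[1L]),
                  log10(config$conc_range_uM[2L]),
                  length.out = config$n_concs)
  pos_concs <- 10^seq(log10(config$conc_range_uM[1L]),
                      log10(config$conc_range_uM[2L]),
                      length.out = config$positive_wells)
  rows <- list()
  plate_counter <- 0L
  for (li in seq_len(nrow(config$labs))) {
    lab <- config$labs[li, ]
    for (si in seq_len(nrow(config$substances))) {
      sub <- config$substances[si, ]
      for (pl in seq_len(config$plates_per_substance)) {
        plate_counter <- plate_counter + 1L
        plate_id <- sprintf("%s_P%04d", lab$lab_id, plate_counter)
        week_id <- sprintf("W%02d", ((pl - 1L) %% config$weeks) + 1L)
        # test wells
        test <- .simulate_wells(
          n = config$embryos_per_conc * config$n_concs,
          conc = rep(concs, each = config$embryos_per_conc),
          lab = lab, sub = sub, mort24_frac = config$mort24_frac)
        test$role <- "test"; test$substance_id <- sub$substance_id
        # vehicle wells: background rates only
        veh <- .simulate_wells(
          n = config$vehicle_wells, conc = rep(0, config$vehicle_wells),
          lab = lab, sub = NULL, mort24_frac = config$mort24_frac)
        veh$role <- "vehicle"; veh$substance_id <- "vehicle_control"
        # positive control: one embryo per concentration
        pc <- config$positive_control$log10_ec50
        pc_ec50 <- if (!is.null(names(pc)) && lab$lab_id %in% names(pc)) {
          pc[[lab$lab_id]]
        } else {
          median(unlist(pc))                  # labs without their own value
        }
        pos_sub <- list(active = TRUE,
                        log10_ec50_mort = pc_ec50,
                        log10_ec50_malf = pc_ec50 - 0.2,
                        hill_slope = config$positive_control$hill_slope)
        pos <- .simulate_wells(
          n = config$positive_wells, conc = pos_concs,
          lab = lab, sub = pos_sub, mort24_frac = config$mort24_frac,
          shift = 0)  # positive-control EC50s are already lab-specific
        pos$role <- "positive"; pos$substance_id <- "positive_control"
        plate <- rbind(test, veh, pos)
        plate$lab_id <- lab$lab_id
        plate$plate_id <- plate_id
        plate$week_id <- week_id
        plate$well_id <- sprintf("%s%02d",
                                 rep(LETTERS[1:8], length.out = nrow(plate)),
                                 ceiling(seq_len(nrow(plate)) / 8))
        rows[[length(rows) + 1L]] <- plate
      }
    }
  }
  wells <- do.call(rbind, rows)
  wells <- wells[, WELL_COLUMNS]
  vocab <- .synthetic_vocabulary(unique(wells$lab_id))
  ds <- study_dataset(wells, vocabulary = vocab)
  attr(ds, "config") <- config
  ds
}

# Simulate n embryos at the given concentrations for one lab/substance.
# One latent uniform per embryo gives nested death thresholds; malformation
# is drawn among survivors. Inactive substances (sub NULL or active FALSE)
# expose embryos to background rates only.
.simulate_wells <- function(n, conc, lab, sub, mort24_frac,
                            shift = lab$potency_shift_log10) {
  if (is.null(sub) || !isTRUE(sub$active)) {
    p120 <- rep(lab$background_mortality_p, n)
    pm <- rep(lab$background_malformation_p, n)
  } else {
    p120 <- .hill_p(conc, lab$background_mortality_p,
                    sub$log10_ec50_mort, sub$hill_slope, shift)
    pm <- .hill_p(conc, lab$background_malformation_p,
                  sub$log10_ec50_malf, sub$hill_slope, shift)
  }
  p24 <- mort24_frac * p120
  u <- runif(n)
  dead_24 <- u < p24
  dead_120 <- u < p120
  malformed <- !dead_120 & (runif(n) < pm)
  data.frame(
    conc_uM = conc, dead_24 = dead_24, dead_120 = dead_120,
    phenotypes = ifelse(malformed,
                        sample(c("generic_edema", "generic_axis_defect",
                                 "generic_craniofacial_defect"),
                               n, replace = TRUE),
                        ""),
    stringsAsFactors = FALSE)
}

.synthetic_vocabulary <- function(lab_ids) {
  terms <- data.frame(
    lab_term = c("generic_edema", "generic_axis_defect",
                 "generic_craniofacial_defect"),
    harmonized_class = c("edema", "axis", "craniofacial"),
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(lab_ids, function(l)
    cbind(data.frame(lab_id = l, stringsAsFactors = FALSE), terms)))
}

#' Analytic point of departure of a synthetic substance
#'
#' Closed-form inversion of the generating hill curve at the excess-risk
#' threshold: the concentration where the true affected probability first
#' exceeds `background + (bmr/100) * (1 - background)`, i.e. where the
#' hill term equals `bmr/100`.
#'
#' @param config a [synthetic_study_config()].
#' @param substance_id substance to invert (must be active).
#' @param lab_id lab whose potency shift applies.
#' @param endpoint one of [screen_endpoints()]; the composite endpoint
#'   uses the (more sensitive) malformation curve.
#' @param bmr benchmark response in percent.
#' @return Concentration in uM.
#' @export
true_pod <- function(config, substance_id, lab_id,
                     endpoint = "MalformedAny+Mort@120", bmr = 10) {
  stopifnot(inherits(config, "synthetic_study_config"))
  .check_bmr(bmr)
  endpoint <- match.arg(endpoint, screen_endpoints())
  sub <- config$substances[config$substances$substance_id == substance_id, ]
  if (nrow(sub) != 1L) .stopf("unknown substance '%s'", substance_id)
  if (!isTRUE(sub$active)) {
    .stopf("substance '%s' is inactive; it has no point of departure", substance_id)
  }
  lab <- config$labs[config$labs$lab_id == lab_id, ]
  if (nrow(lab) != 1L) .stopf("unknown lab '%s'", lab_id)
  B <- bmr / 100
  if (endpoint == "MalformedAny+Mort@120") {
    # exact inversion of the composite curve p_mort + (1 - p_mort) * p_malf
    shift <- lab$potency_shift_log10
    paff <- function(c) {
      pm <- .hill_p(c, lab$background_mortality_p, sub$log10_ec50_mort,
                    sub$hill_slope, shift)
      pf <- .hill_p(c, lab$background_malformation_p, sub$log10_ec50_malf,
                    sub$hill_slope, shift)
      pm + (1 - pm) * pf
    }
    a0 <- lab$background_mortality_p +
      (1 - lab$background_mortality_p) * lab$background_malformation_p
    target <- a0 + B * (1 - a0)
    lo <- sub$log10_ec50_malf + shift - 12
    hi <- max(sub$log10_ec50_malf, sub$log10_ec50_mort) + shift + 12
    root <- stats::uniroot(function(lc) paff(10^lc) - target, c(lo, hi),
                           tol = 1e-12)
    return(10^root$root)
  }
  if (endpoint == "Mortality@24") {
    # p24(c) = f * p120(c): solve for the hill term H where p24 crosses
    # its own background plus B times the remaining headroom
    f <- config$mort24_frac
    pbg <- lab$background_mortality_p
    H <- B * (1 - f * pbg) / (f * (1 - pbg))
    if (H >= 1) {
      .stopf("the 24-hpf mortality curve never reaches the excess-risk threshold")
    }
    ec50 <- sub$log10_ec50_mort
  } else {                                    # Mortality@120: one pure hill
    H <- B
    ec50 <- sub$log10_ec50_mort
  }
  # hill term reaches H at c = EC50 * (H / (1 - H))^(1 / slope)
  10^(ec50 + lab$potency_shift_log10) * (H / (1 - H))^(1 / sub$hill_slope)
}
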