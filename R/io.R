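# Readers/writers for the observation CSV dialect and the aggregate-data
# JSON format, plus the case-study fixture generator.
#
# Observation CSV: minimal NONMEM-like long format with columns ID, TIME,
# DV, AMT, EVID. Observation rows have EVID = 0 and a DV; dose rows have
# EVID = 1 and an AMT. Times in hours, concentrations in mg/L, doses in mg.

#' Write an individual dataset to long-format CSV
#'
#' @param data An [individual_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(data, path) {
  des <- data$design
  rows <- lapply(seq_len(nrow(data$Y)), function(i) {
    id <- data$subject_ids[i]
    rbind(data.frame(ID = id, TIME = des$dose_time, DV = NA_real_,
                     AMT = des$dose_amount, EVID = 1L),
          data.frame(ID = id, TIME = des$times, DV = data$Y[i, ],
                     AMT = NA_real_, EVID = 0L))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an individual dataset from long-format CSV
#'
#' Requires a balanced observation grid: every subject must have exactly one
#' observation at every time in the shared grid. The design (times, dose) is
#' inferred from the observation and dose rows.
#'
#' @param path Input CSV with columns ID, TIME, DV and optionally AMT, EVID.
#' @return An [individual_dataset()].
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ID", "TIME", "DV")
  if (!all(need %in% names(df)))
    stop("missing required columns: ", paste(setdiff(need, names(df)),
                                             collapse = ", "))
  if (!"EVID" %in% names(df)) df$EVID <- 0L
  obs <- df[df$EVID == 0, ]
  if (!is.numeric(obs$TIME) || !is.numeric(obs$DV))
    stop("TIME and DV must be numeric")
  if (anyNA(obs$DV)) stop("missing DV values in observation rows")
  times <- sort(unique(obs$TIME))
  ids <- unique(df$ID)
  Y <- matrix(NA_real_, length(ids), length(times))
  for (i in seq_along(ids)) {
    oi <- obs[obs$ID == ids[i], ]
    oi <- oi[order(oi$TIME), ]
    if (length(oi$TIME) != length(times) || any(oi$TIME != times)) {
      missing_t <- setdiff(times, oi$TIME)
      stop("unbalanced observation grid: subject ", ids[i],
           if (length(missing_t)) paste0(" lacks time(s) ",
                                         paste(missing_t, collapse = ", "))
           else " has duplicated or extra times")
    }
    Y[i, ] <- oi$DV
  }
  doses <- df[df$EVID == 1, ]
  dose_amount <- if (nrow(doses)) doses$AMT[1] else 0
  dose_time <- if (nrow(doses)) doses$TIME[1] else 0
  design <- pk_design(times, dose_amount = dose_amount, dose_time = dose_time,
                      n_subjects = length(ids))
  individual_dataset(Y, design, subject_ids = ids)
}

#' Write aggregate data to JSON
#'
#' Format: `{"times": [...], "n_subjects": N, "mean": [...], "cov": [[...]]}`
#' with the covariance stored dense row-major; round-trips at full double
#' precision.
#'
#' @param agg An [aggregate_data()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aggregate_json <- function(agg, path) {
  # digits = I(17): 17 significant digits, the exact-round-trip width for
  # IEEE doubles
  jsonlite::write_json(list(times = agg$times, n_subjects = agg$n_subjects,
                            mean = agg$ybar, cov = agg$V),
                       path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read aggregate data from JSON
#'
#' A covariance matrix asymmetric within 1e-8 relative tolerance is
#' symmetrized with a message; larger asymmetry, dimension mismatches, a
#' materially negative eigenvalue, or a nonzero covariance with a single
#' subject are rejected.
#'
#' @param path Input JSON file.
#' @return An [aggregate_data()].
#' @export
read_aggregate_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("times", "n_subjects", "mean", "cov")
  if (!all(need %in% names(x)))
    stop("missing fields: ", paste(setdiff(need, names(x)), collapse = ", "))
  V <- as.matrix(x$cov)
  K <- length(x$mean)
  if (!all(dim(V) == K)) stop("cov must be ", K, " x ", K)
  asym <- max(abs(V - t(V)))
  if (asym > 1e-8 * max(1, max(abs(V))))
    stop("cov is asymmetric beyond tolerance (max deviation ", format(asym), ")")
  if (asym > 0) message("symmetrizing cov (max asymmetry ", format(asym), ")")
  aggregate_data(x$mean, (V + t(V)) / 2, x$n_subjects, times = x$times)
}

# Case-study configurations; the values define the study conditions
# throughout the package's tests and examples.
.case2_params <- function() pop_params(beta = c(CL = 5, Vc = 10, Vp = 30,
                                                Q = 10, ka = 1),
                                       omega = rep(0.3^2, 5),
                                       sigma_add2 = 0.2^2)

.case2_design <- function(n_subjects = 100)
  pk_design(c(0.1, 0.25, 0.5, 1, 2, 3, 5, 8, 12), dose_amount = 100,
            dose_time = 0, n_subjects = n_subjects)

# Transit-absorption generator: lognormal IIV (log-SD 0.3) on the mean
# transit time only; the transit-compartment count is structurally fixed at
# 2 and the disposition constants carry no inter-individual variability.
.case4_gen_params <- function() pop_params(beta = c(MTT = 1, CL = 5, Vc = 10,
                                                    Vp = 30, Q = 10),
                                           omega = c(0.3^2, 0, 0, 0, 0),
                                           sigma_add2 = 0.2^2)

.wang_params <- function() pop_params(beta = 0.5, omega = 0.04,
                                      sigma_add2 = 0.1)

#' Generate case-study fixtures
#'
#' Writes the configuration (and, where applicable, simulated data) for the
#' built-in case studies into a directory:
#' \describe{
#'   \item{wang_model}{Model/parameter configuration only (`beta = 0.5`,
#'     `omega^2 = 0.04`, `sigma^2 = 0.1`); the 10-subject observation table
#'     itself is an external published dataset supplied as a CSV.}
#'   \item{case2}{Two-compartment oral configuration (CL 5, Vc 10 L, Vp 30
#'     L, Q 10 L/h, ka 1/h; lognormal IIV log-SD 0.3 on all; additive SD 0.2
#'     mg/L; 100 mg dose; 9 sampling times from 0.1 to 12 h) plus a
#'     simulated dataset of `n_subjects` subjects.}
#'   \item{case4_generator}{The transit-absorption generator (MTT 1 h, 2
#'     transit compartments, log-SD 0.3) paired with the case2 analytic
#'     model configuration.}
#' }
#'
#' @param case One of "wang_model", "case2", "case4_generator".
#' @param dir Output directory (created if needed).
#' @param seed Simulation seed.
#' @param n_subjects Subjects to simulate for "case2" (default 100).
#' @return List with the resolved configuration and written file paths.
#' @export
make_fixture <- function(case = c("wang_model", "case2", "case4_generator"),
                         dir = ".", seed = 1L, n_subjects = 100L) {
  case <- match.arg(case)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, paste0(case, "_config.json"))
  if (case == "wang_model") {
    cfg <- list(case = case, model = "wang", residual_kind = "additive",
                beta = 0.5, omega2 = 0.04, sigma2 = 0.1, seed = seed,
                note = "observation table supplied externally as CSV")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    return(list(config = cfg, files = cfg_path))
  }
  if (case == "case2") {
    p <- .case2_params(); d <- .case2_design(n_subjects)
    cfg <- list(case = case, model = "twocomp_oral",
                residual_kind = "additive", beta = as.list(p$beta),
                omega_diag = diag(p$omega), sigma_add2 = p$sigma_add2,
                times = d$times, dose_amount = d$dose_amount,
                dose_time = d$dose_time, n_subjects = d$n_subjects,
                seed = seed)
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    dat <- simulate_individuals(pk_model("twocomp_oral"), p, d, seed = seed)
    csv_path <- file.path(dir, "case2_observations.csv")
    write_observations_csv(dat, csv_path)
    agg_path <- file.path(dir, "case2_aggregate.json")
    write_aggregate_json(aggregate_observed(dat), agg_path)
    return(list(config = cfg, files = c(cfg_path, csv_path, agg_path)))
  }
  # case4_generator
  p <- .case4_gen_params(); d <- .case2_design(n_subjects)
  cfg <- list(case = case, gen_model = "transit2", ana_model = "twocomp_oral",
              residual_kind = "additive", gen_beta = as.list(p$beta),
              gen_omega_diag = diag(p$omega), gen_sigma_add2 = p$sigma_add2,
              ana_beta = as.list(.case2_params()$beta),
              ana_omega_diag = diag(.case2_params()$omega),
              ana_sigma_add2 = .case2_params()$sigma_add2,
              times = d$times, dose_amount = d$dose_amount,
              dose_time = d$dose_time, n_subjects = d$n_subjects, seed = seed)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  list(config = cfg, files = cfg_path)
}
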