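#' Shipped lookup tables
#'
#' The original database carried lookup tables defining flag and weighting
#' codes; their definitions are occasionally incomplete or speculative
#' because some original meanings were lost. The shipped lookups cover the
#' documented subset and mark speculative entries (`attested = "no"`);
#' codes outside the tables pass through the pipeline verbatim.
#'
#' @return A data.frame.
#' @export
frf_flag_codes <- function() {
  utils::read.csv(system.file("extdata", "flag_codes.csv",
                              package = "reconkit"),
                  colClasses = "character")
}

#' @rdname frf_flag_codes
#' @export
frf_weighting_codes <- function() {
  x <- utils::read.csv(system.file("extdata", "weighting_codes.csv",
                                   package = "reconkit"),
                       colClasses = "character")
  x$code <- as.integer(x$code)
  x
}

.lookup_cache <- new.env(parent = emptyenv())

# the estimation mapper consults this table for every date column; read the
# shipped CSV once per session
.weighting_codes_cached <- function() {
  if (is.null(.lookup_cache$wcodes))
    .lookup_cache$wcodes <- frf_weighting_codes()
  .lookup_cache$wcodes
}

#' @rdname frf_flag_codes
#' @export
parish_weight_rules <- function() {
  x <- utils::read.csv(system.file("extdata", "parish_weights.csv",
                                   package = "reconkit"),
                       colClasses = "character")
  x$fertility_weight <- as.numeric(x$fertility_weight)
  x
}
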