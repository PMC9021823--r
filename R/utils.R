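# Internal helpers shared across the package.

SUBSCALES <- c("ca", "sa", "sc")

# Population (divide-by-n) standard deviation; the default convention for
# within-person zone widths, where the recalled occasions are a fixed design
# rather than a sample from a larger population of occasions.
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# SD under either convention; sample SD of a single value is reported as 0
# so degenerate one-row summaries stay numeric.
sd_by <- function(x, method = c("population", "sample")) {
  method <- match.arg(method)
  if (method == "population") return(pop_sd(x))
  if (length(x) < 2) return(0)
  stats::sd(x)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

stop_izof <- function(..., class) {
  stop(structure(
    class = c(class, "izof_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Descriptive row used by the report builders: mean, sd, median, min, max.
describe <- function(x) {
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    median = stats::median(x), min = min(x), max = max(x))
}
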