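# internal helpers

.stopf <- function(fmt, ..., class = "ipclust_error") {
  stop(errorCondition(sprintf(fmt, ...),
                      class = unique(c(class, "ipclust_error"))))
}

.formatError <- function(fmt, ...) .stopf(fmt, ..., class = "ipclust_format_error")
.valueError <- function(fmt, ...) .stopf(fmt, ..., class = "ipclust_value_error")
.argError <- function(fmt, ...) .stopf(fmt, ..., class = "ipclust_argument_error")

# coerce GenotypeData or matrix to a plain numeric matrix
.asGenoMatrix <- function(x) {
  if (is(x, "GenotypeData")) genotypes(x) else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}
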