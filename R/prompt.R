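# Bilingual chatbot prompt assembly and a stubbed transport interface.

prompt_system_en <- paste0(
  "You are a chatbot integrated into a smart mirror system. This smart ",
  "mirror uses a camera to extract real-time estimates of the user’s age, ",
  "emotion, heart rate, and oxygen saturation. These values are AI-based ",
  "estimations and may not always be accurate—please consider this when ",
  "responding. Provide a short health and wellness summary (max 3 ",
  "sentences), identify possible signs of stress, fatigue, or health ",
  "concerns, and offer a simple lifestyle or recovery suggestion.")

# Korean scaffolding is a documented translation (the deployed GUI is
# bilingual but only the English template is canonical).
prompt_system_ko <- paste0(
  "당신은 스마트 미러 시스템에 ",
  "통합된 챗봇입니다. 이 스마트 ",
  "미러는 카메라로 사용자의 나이, ",
  "감정, 심박수, 산소 포화도를 실시간으로 ",
  "추정합니다. 이 값들은 AI 기반 추정치이므로 ",
  "항상 정확하지 않을 수 있으니 응답 시 ",
  "이를 고려하세요. 건강 및 웰빙 요약(최대 3문장)을 ",
  "제공하고, 스트레스·피로·건강 문제의 징후를 ",
  "파악하며, 간단한 생활 습관 또는 회복 방법을 ",
  "제안하세요.")

#' Prompt context from a triggered session snapshot
#'
#' @param age_bucket age label (e.g. `"25"` or `"20s"`).
#' @param emotion emotion label (the `expression` slot).
#' @param hr_bpm heart rate, integer bpm, > 0.
#' @param spo2_pct SpO2, integer percent in `[0, 100]`.
#' @param language `"en"` or `"ko"`.
#' @return object of class `prompt_context`.
#' @export
prompt_context <- function(age_bucket, emotion, hr_bpm, spo2_pct,
                           language = c("en", "ko")) {
  language <- match.arg(language)
  missing_slots <- c(
    if (missing(age_bucket) || is.null(age_bucket) || is.na(age_bucket)) "age",
    if (missing(emotion) || is.null(emotion) || is.na(emotion)) "expression",
    if (missing(hr_bpm) || is.null(hr_bpm) || is.na(hr_bpm)) "bpm",
    if (missing(spo2_pct) || is.null(spo2_pct) || is.na(spo2_pct)) "spo2")
  if (length(missing_slots))
    abort_context(paste("missing prompt slots:", paste(missing_slots, collapse = ", ")),
                  slots = missing_slots)
  if (hr_bpm <= 0) abort_context("hr_bpm must be positive")
  if (spo2_pct < 0 || spo2_pct > 100) abort_context("spo2_pct must lie in [0, 100]")
  structure(list(age_bucket = as.character(age_bucket),
                 emotion = as.character(emotion),
                 hr_bpm = as.integer(round(hr_bpm)),
                 spo2_pct = as.integer(round(spo2_pct)),
                 language = language),
            class = "prompt_context")
}

#' Build the chatbot prompt
#'
#' Pure function assembling the system and user messages. For `language =
#' "en"` the system part is the canonical template verbatim (including the
#' uncertainty disclaimer and the max-3-sentences constraint) and the user
#' part interpolates the four slots in the fixed order
#' `Age, Emotion, Heart Rate, SpO2`. The Korean template mirrors the slot
#' order with translated scaffolding (a documented translation, not claimed
#' verbatim).
#'
#' @param ctx a [prompt_context()].
#' @return list with `system` and `user` character scalars, class
#'   `mirror_prompt`.
#' @export
build_prompt <- function(ctx) {
  if (!inherits(ctx, "prompt_context"))
    abort_context("`ctx` must be a prompt_context")
  user <- sprintf("User profile: Age: %s, Emotion: %s, Heart Rate: %d BPM, SpO2: %d%%.",
                  ctx$age_bucket, ctx$emotion, ctx$hr_bpm, ctx$spo2_pct)
  sys <- switch(ctx$language, en = prompt_system_en, ko = prompt_system_ko)
  structure(list(system = sys, user = user, language = ctx$language),
            class = "mirror_prompt")
}

#' @export
print.mirror_prompt <- function(x, ...) {
  cat("[system]", x$system, "\n[user]", x$user, "\n")
  invisible(x)
}

#' Send a prompt through a transport
#'
#' The transport is any caller-supplied function taking a `mirror_prompt`
#' and returning the response text; the LLM/network side is out of scope and
#' stubbed for tests (see [stub_transport()]). Round-trip latency is attached
#' as an attribute. Transport failures surface as a chat error carrying the
#' cause; there is no retry.
#'
#' @param prompt a `mirror_prompt` from [build_prompt()].
#' @param transport function `(prompt) -> character`.
#' @return response text with attribute `latency_s`.
#' @export
send_to_chat <- function(prompt, transport = stub_transport()) {
  if (!is.function(transport)) abort_config("`transport` must be a function")
  t0 <- Sys.time()
  resp <- tryCatch(transport(prompt), error = function(e)
    abort_chat(paste("transport failed:", conditionMessage(e)), cause = e))
  attr(resp, "latency_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  resp
}

#' Canned-response transport stub
#'
#' @param response fixed text to return; `NULL` echoes the user part of the
#'   prompt.
#' @return a transport function for [send_to_chat()].
#' @export
stub_transport <- function(response = NULL) {
  function(prompt) {
    if (is.null(response)) paste(prompt$system, prompt$user) else response
  }
}
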