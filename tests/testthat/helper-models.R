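# Shared lazily-built fixtures. Heavy objects (the desk-scale pretrained
# model and its corpus) are built once per test run and reused across
# files. Sizes are the package's desk-scale study conditions: a 5,000-line
# synthetic corpus, a 200-token tokenizer and a 2-layer/64-hidden encoder
# pre-trained for one epoch.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

desk_corpus <- function() memo("corpus", function() {
  gen_corpus(fixture_spec(n_molecules = 5000, seed = 101))
})

desk_tokenizer <- function() memo("tokenizer", function() {
  train_unigram(desk_corpus()$smiles, 200, seed = 1)
})

desk_model <- function() memo("model", function() {
  pretrain(desk_corpus()$smiles, desk_tokenizer(),
           config = desk_preset(200), plan = batch_plan(8L, 4L),
           epochs = 1L, seed = 7L)
})

# same architecture and tokenizer, untrained weights (same init seed as the
# trained model, so the comparison isolates the effect of pre-training)
desk_random_model <- function() memo("random_model", function() {
  m <- desk_model()
  set.seed(7L)
  m$encoder <- build_encoder(desk_preset(200))
  m$trace <- m$trace[0, ]
  m$model_id <- "random-init"
  m
})

desk_target <- function() memo("target", function() {
  gen_screening_target(25, 150, seed = 11)
})

desk_labeled <- function() memo("labeled", function() {
  gen_labeled_dataset(500, "nitro", noise_rate = 0, seed = 21)
})

desk_finetuned <- function() memo("finetuned", function() {
  finetune_single(desk_model(), desk_labeled(),
                  finetune_config(epochs = 10L, seed = 3L))
})

# a light tokenizer + untrained encoder for cheap mechanical tests
tiny_bundle <- function() memo("tiny", function() {
  corpus <- desk_corpus()$smiles[1:150]
  tok <- train_unigram(corpus, 80, seed = 2)
  set.seed(4)
  enc <- build_encoder(encoder_config(n_layers = 2L, n_heads = 2L,
                                      hidden = 16L, intermediate = 32L,
                                      max_positions = 514L,
                                      vocab_size = tok$vocab_size,
                                      dropout = 0))
  structure(list(encoder = enc, tokenizer = tok, trace = data.frame(),
                 model_id = "tiny"), class = "smilesbert_model")
})
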