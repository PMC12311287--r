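Package: kgfusion
Title: Knowledge Graph Completion by Coupling Tensor Decomposition with
    Query-Guided Subgraph Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Link prediction on multi-relational (biomedical) knowledge
    graphs by a hybrid of global semantics and local structure: a canonical
    polyadic (CP) factorization of the graph tensor supplies entity and
    relation embeddings and a trilinear semantic score, while a query-guided
    subgraph is grown by attentive message passing with recurrent
    (LSTM-gated) contextual refinement of relation embeddings and
    differentiable top-K relevance filtering. The two branches are fused
    into a single triple score and trained jointly with a multi-class
    log-loss and an N3 regularizer. Includes filtered-ranking evaluation
    (MRR, Hit@k), ablation variants, and seeded synthetic knowledge-graph
    generators (planted low-rank tensors and compositional multi-hop rules)
    so the whole pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
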