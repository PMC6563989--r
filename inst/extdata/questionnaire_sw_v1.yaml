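# FIMD validation questionnaire, same-weight (SW) system, version sw-1.0.
# 100 points split equally over 8 domains (12.5 each), then equally over the
# questions within each domain. Question 2.2 is a grouping label; only its
# four sub-items (2.2.1-2.2.4) are answerable and carry weight.
version: sw-1.0
domains:
  - id: 1
    name: Epidemiological
    weight: 12.5
  - id: 2
    name: Symptomatology and Natural History
    weight: 12.5
  - id: 3
    name: Genetic
    weight: 12.5
  - id: 4
    name: Biochemical
    weight: 12.5
  - id: 5
    name: Aetiological
    weight: 12.5
  - id: 6
    name: Histological
    weight: 12.5
  - id: 7
    name: Pharmacological
    weight: 12.5
  - id: 8
    name: Endpoint
    weight: 12.5
questions:
  - id: "1.1"
    domain: 1
    weight: 6.25
    text: "Is the model able to simulate the disease in the relevant sexes?"
  - id: "1.2"
    domain: 1
    weight: 6.25
    text: "Is the model able to simulate the disease in the relevant age groups (e.g. juvenile, adult or ageing)?"
  - id: "2.1"
    domain: 2
    weight: 2.5
    text: "Is the model able to replicate the symptoms and co-morbidities commonly present in this disease? If so, which ones?"
  - id: "2.2.1"
    domain: 2
    weight: 2.5
    text: "Is the natural history of the disease similar to human's regarding: time to onset"
  - id: "2.2.2"
    domain: 2
    weight: 2.5
    text: "Is the natural history of the disease similar to human's regarding: disease progression"
  - id: "2.2.3"
    domain: 2
    weight: 2.5
    text: "Is the natural history of the disease similar to human's regarding: duration of symptoms"
  - id: "2.2.4"
    domain: 2
    weight: 2.5
    text: "Is the natural history of the disease similar to human's regarding: severity"
  - id: "3.1"
    domain: 3
    weight: 4.17
    text: "Does this species also have orthologous genes and/or proteins involved in the human disease?"
  - id: "3.2"
    domain: 3
    weight: 4.17
    text: "If so, are the relevant genetic mutations or alterations also present in the orthologous genes/proteins?"
  - id: "3.3"
    domain: 3
    weight: 4.16
    text: "If so, is the expression of such orthologous genes and/or proteins similar to the human condition?"
  - id: "4.1"
    domain: 4
    weight: 3.125
    text: "If there are known pharmacodynamic (PD) biomarkers related to the pathophysiology of the disease, are they also present in the model?"
  - id: "4.2"
    domain: 4
    weight: 3.125
    text: "Do these PD biomarkers behave similarly to humans'?"
  - id: "4.3"
    domain: 4
    weight: 3.125
    text: "If there are known prognostic biomarkers related to the pathophysiology of the disease, are they also present in the model?"
  - id: "4.4"
    domain: 4
    weight: 3.125
    text: "Do these prognostic biomarkers behave similarly to humans'?"
  - id: "5.1"
    domain: 5
    weight: 12.5
    text: "Is the aetiology of the disease similar to humans'?"
  - id: "6.1"
    domain: 6
    weight: 12.5
    text: "Do the histopathological structures in relevant tissues resemble the ones found in humans?"
  - id: "7.1"
    domain: 7
    weight: 4.17
    text: "Are effective drugs in humans also effective in this model?"
  - id: "7.2"
    domain: 7
    weight: 4.17
    text: "Are ineffective drugs in humans also ineffective in this model?"
  - id: "7.3"
    domain: 7
    weight: 4.16
    text: "Have drugs with different mechanisms of action and acting on different pathways been tested in this model? If so, which?"
  - id: "8.1"
    domain: 8
    weight: 6.25
    text: "Are the endpoints used in preclinical studies the same or translatable to the clinical endpoints?"
  - id: "8.2"
    domain: 8
    weight: 6.25
    text: "Are the methods used to assess preclinical endpoints comparable to the ones used to assess related clinical endpoints?"
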