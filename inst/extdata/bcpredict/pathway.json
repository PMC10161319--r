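{
  "stages": ["invitation", "questionnaire", "density", "density_implementation", "snp", "risk_letter", "consultation"],
  "strategies": {
    "TC": {
      "components": ["invitation", "questionnaire", "risk_letter", "consultation"],
      "risk_set": {
        "@p_high": "p_high_tc",
        "@p_mod": "p_mod_tc"
      }
    },
    "TC_VBD": {
      "components": ["invitation", "questionnaire", "risk_letter", "consultation", "volpara", "volpara_implementation_issues"],
      "risk_set": {
        "@p_high": "p_high_vbd",
        "@p_mod": "p_mod_vbd"
      }
    },
    "TC_VBD_SNP": {
      "components": ["invitation", "questionnaire", "risk_letter", "consultation", "volpara", "volpara_implementation_issues", "snp"],
      "risk_set": {
        "@p_high": "p_high_snp",
        "@p_mod": "p_mod_snp"
      }
    }
  },
  "settings": {
    "trial": {
      "exclude_items": [],
      "exclude_components": [],
      "substitute": []
    },
    "nhs": {
      "exclude_items": ["inv_print", "inv_staff", "inv_post", "letter_retrieve", "risk_pack"],
      "exclude_components": "volpara_implementation_issues",
      "substitute": {
        "consult_high": "consult_high_nhs",
        "consult_mod": "consult_mod_nhs"
      }
    }
  },
  "root": {
    "type": "seq",
    "children": [
      {
        "type": "act",
        "component": "invitation",
        "items": [
          "inv_print",
          "inv_staff",
          "inv_post"
        ]
      },
      {
        "type": "chance",
        "id": "q_mode",
        "component": "questionnaire",
        "branches": [
          {
            "p": "p_paper",
            "child": {
              "type": "seq",
              "children": [
                {
                  "type": "act",
                  "component": null,
                  "items": [
                    "q_print",
                    "q_post",
                    "q_entry"
                  ]
                },
                {
                  "type": "chance",
                  "id": "q_followup",
                  "component": null,
                  "branches": [
                    {
                      "p": "p_followup",
                      "child": {
                        "type": "act",
                        "component": null,
                        "items": [
                          "q_phone"
                        ]
                      }
                    },
                    {
                      "p": "~",
                      "child": null
                    }
                  ]
                }
              ]
            }
          },
          {
            "p": "~",
            "child": null
          }
        ]
      },
      {
        "type": "act",
        "component": "volpara",
        "items": [
          "volpara"
        ]
      },
      {
        "type": "chance",
        "id": "vol_fail",
        "component": "volpara_implementation_issues",
        "branches": [
          {
            "p": "p_fail",
            "child": {
              "type": "act",
              "component": null,
              "items": [
                "vol_followup"
              ]
            }
          },
          {
            "p": "~",
            "child": null
          }
        ]
      },
      {
        "type": "chance",
        "id": "vol_birads",
        "component": "volpara_implementation_issues",
        "branches": [
          {
            "p": "p_birads",
            "child": {
              "type": "act",
              "component": null,
              "items": [
                "birads_read"
              ]
            }
          },
          {
            "p": "~",
            "child": null
          }
        ]
      },
      {
        "type": "act",
        "component": "volpara_implementation_issues",
        "items": [
          "aerial"
        ]
      },
      {
        "type": "act",
        "component": "snp",
        "items": [
          "saliva_collection",
          "snp_staff",
          "snp_consumables"
        ]
      },
      {
        "type": "act",
        "component": "risk_letter",
        "items": [
          "letter_retrieve",
          "letter_print",
          "letter_fill",
          "letter_post"
        ]
      },
      {
        "type": "chance",
        "id": "risk_category",
        "component": "consultation",
        "branches": [
          {
            "p": "@p_high",
            "child": {
              "type": "chance",
              "id": "uptake_high",
              "component": null,
              "branches": [
                {
                  "p": "p_attend_high",
                  "child": {
                    "type": "act",
                    "component": null,
                    "items": [
                      "organize_appt",
                      "risk_pack",
                      "consult_high"
                    ]
                  }
                },
                {
                  "p": "~",
                  "child": null
                }
              ]
            }
          },
          {
            "p": "@p_mod",
            "child": {
              "type": "chance",
              "id": "uptake_mod",
              "component": null,
              "branches": [
                {
                  "p": "p_attend_mod",
                  "child": {
                    "type": "act",
                    "component": null,
                    "items": [
                      "organize_appt",
                      "risk_pack",
                      "consult_mod"
                    ]
                  }
                },
                {
                  "p": "~",
                  "child": null
                }
              ]
            }
          },
          {
            "p": "~",
            "child": null
          }
        ]
      }
    ]
  }
}
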