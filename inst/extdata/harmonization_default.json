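{
  "comment": "Default recode rules. Only the published recodes are pre-filled; raw code inventories of specific source systems should be added by editing this file.",
  "rules": [
    {
      "target_variable": "sv_type",
      "mapping": {
        "rape": "rape",
        "attempted rape": "rape",
        "serious wounding with sexual motive": "other_sv",
        "other wounding with sexual motive": "other_sv",
        "indecent assault": "other_sv",
        "sexual assault": "other_sv",
        "assault by penetration": "other_sv",
        "voyeurism": "other_sv",
        "sexual bullying": "other_sv",
        "penetration by object": "other_sv",
        "gang related sexual violence": "other_sv",
        "forced sexual activity in public": "other_sv",
        "exposed to sexual images": "other_sv",
        "sexual harassment": "other_sv",
        "sexual exploitation": "other_sv",
        "other_sv": "other_sv"
      },
      "priority_order": [
        "rape",
        "other_sv"
      ],
      "drop_codes": [
        "childhood rape",
        "childhood sexual abuse",
        "non-sexual domestic abuse",
        "other violence or abuse"
      ]
    },
    {
      "target_variable": "perpetrator",
      "mapping": {
        "partner": "domestic",
        "former partner": "domestic",
        "ex-partner": "domestic",
        "spouse": "domestic",
        "family member": "domestic",
        "relative": "domestic",
        "friend": "acquaintance",
        "colleague": "acquaintance",
        "acquaintance": "acquaintance",
        "neighbour": "acquaintance",
        "date": "acquaintance",
        "stranger": "stranger_unknown",
        "unknown": "stranger_unknown",
        "not known": "stranger_unknown",
        "stranger_unknown": "stranger_unknown",
        "domestic": "domestic"
      },
      "priority_order": [
        "domestic",
        "acquaintance",
        "stranger_unknown"
      ]
    },
    {
      "target_variable": "injury",
      "mapping": {
        "none": "no_injury",
        "no impact": "no_injury",
        "bruised": "injury",
        "scratched": "injury",
        "cut": "injury",
        "injured": "injury",
        "memory loss": "injury",
        "physical injuries": "injury",
        "body problems": "injury",
        "gynaecological disorder": "injury",
        "sexually transmitted infection": "injury",
        "no_injury": "no_injury",
        "injury": "injury"
      },
      "priority_order": [
        "injury",
        "no_injury"
      ]
    },
    {
      "target_variable": "gender",
      "mapping": {
        "male": "male",
        "man": "male",
        "transgender male": "male",
        "female": "female",
        "woman": "female",
        "transgender female": "female"
      }
    },
    {
      "target_variable": "relationship_status",
      "mapping": {
        "married": "married_cohabiting",
        "cohabiting": "married_cohabiting",
        "civil partnership": "married_cohabiting",
        "single": "single_widowed",
        "non-resident partner": "single_widowed",
        "widowed": "single_widowed",
        "separated": "separated_divorced",
        "divorced": "separated_divorced",
        "separated_divorced": "separated_divorced",
        "single_widowed": "single_widowed",
        "married_cohabiting": "married_cohabiting"
      }
    },
    {
      "target_variable": "ethnicity",
      "mapping": {
        "white": "white",
        "white british": "white",
        "white other": "white",
        "black": "non_white",
        "asian": "non_white",
        "mixed": "non_white",
        "other ethnicity": "non_white",
        "non_white": "non_white"
      }
    },
    {
      "target_variable": "employment",
      "mapping": {
        "employed": "employed",
        "self-employed": "employed",
        "unemployed": "unemployed",
        "homemaker": "outside_labour_force",
        "retired": "outside_labour_force",
        "unable to work due to illness": "outside_labour_force",
        "student": "student",
        "outside_labour_force": "outside_labour_force"
      }
    },
    {
      "target_variable": "tenure",
      "mapping": {
        "homeowner": "homeowner",
        "owner occupier": "homeowner",
        "lives in own home": "homeowner",
        "renter": "renter",
        "private renter": "renter",
        "social renter": "renter",
        "other": "other",
        "temporary accommodation": "other",
        "living with family or friends": "other"
      }
    }
  ]
}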