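[
  {"scale_id": "global_health", "questionnaire": "C30", "items": [29, 30], "range": 6, "polarity": "global"},
  {"scale_id": "physical_functioning", "questionnaire": "C30", "items": [1, 2, 3, 4, 5], "range": 3, "polarity": "functional"},
  {"scale_id": "role_functioning", "questionnaire": "C30", "items": [6, 7], "range": 3, "polarity": "functional"},
  {"scale_id": "emotional_functioning", "questionnaire": "C30", "items": [21, 22, 23, 24], "range": 3, "polarity": "functional"},
  {"scale_id": "cognitive_functioning", "questionnaire": "C30", "items": [20, 25], "range": 3, "polarity": "functional"},
  {"scale_id": "social_functioning", "questionnaire": "C30", "items": [26, 27], "range": 3, "polarity": "functional"},
  {"scale_id": "fatigue", "questionnaire": "C30", "items": [10, 12, 18], "range": 3, "polarity": "symptom"},
  {"scale_id": "nausea_vomiting", "questionnaire": "C30", "items": [14, 15], "range": 3, "polarity": "symptom"},
  {"scale_id": "pain", "questionnaire": "C30", "items": [9, 19], "range": 3, "polarity": "symptom"},
  {"scale_id": "dyspnea", "questionnaire": "C30", "items": [8], "range": 3, "polarity": "symptom"},
  {"scale_id": "insomnia", "questionnaire": "C30", "items": [11], "range": 3, "polarity": "symptom"},
  {"scale_id": "appetite_loss", "questionnaire": "C30", "items": [13], "range": 3, "polarity": "symptom"},
  {"scale_id": "constipation", "questionnaire": "C30", "items": [16], "range": 3, "polarity": "symptom"},
  {"scale_id": "diarrhea", "questionnaire": "C30", "items": [17], "range": 3, "polarity": "symptom"},
  {"scale_id": "financial_difficulties", "questionnaire": "C30", "items": [28], "range": 3, "polarity": "symptom"},
  {"scale_id": "urinary_frequency", "questionnaire": "CR29", "items": [31, 32], "range": 3, "polarity": "symptom"},
  {"scale_id": "blood_mucus_stool", "questionnaire": "CR29", "items": [38, 39], "range": 3, "polarity": "symptom"},
  {"scale_id": "body_image", "questionnaire": "CR29", "items": [45, 46, 47], "range": 3, "polarity": "functional"},
  {"scale_id": "urinary_incontinence", "questionnaire": "CR29", "items": [33], "range": 3, "polarity": "symptom"},
  {"scale_id": "dysuria", "questionnaire": "CR29", "items": [34], "range": 3, "polarity": "symptom"},
  {"scale_id": "abdominal_pain", "questionnaire": "CR29", "items": [35], "range": 3, "polarity": "symptom"},
  {"scale_id": "buttock_pain", "questionnaire": "CR29", "items": [36], "range": 3, "polarity": "symptom"},
  {"scale_id": "bloated_feeling", "questionnaire": "CR29", "items": [37], "range": 3, "polarity": "symptom"},
  {"scale_id": "dry_mouth", "questionnaire": "CR29", "items": [40], "range": 3, "polarity": "symptom"},
  {"scale_id": "hair_loss", "questionnaire": "CR29", "items": [41], "range": 3, "polarity": "symptom"},
  {"scale_id": "taste", "questionnaire": "CR29", "items": [42], "range": 3, "polarity": "symptom"},
  {"scale_id": "anxiety", "questionnaire": "CR29", "items": [43], "range": 3, "polarity": "functional"},
  {"scale_id": "flatulence", "questionnaire": "CR29", "items": [49], "range": 3, "polarity": "symptom"},
  {"scale_id": "fecal_incontinence", "questionnaire": "CR29", "items": [50], "range": 3, "polarity": "symptom"},
  {"scale_id": "sore_skin", "questionnaire": "CR29", "items": [51], "range": 3, "polarity": "symptom"},
  {"scale_id": "embarrassment", "questionnaire": "CR29", "items": [54], "range": 3, "polarity": "symptom"},
  {"scale_id": "sexual_interest_men", "questionnaire": "CR29", "items": [56], "range": 3, "polarity": "functional"},
  {"scale_id": "sexual_interest_women", "questionnaire": "CR29", "items": [58], "range": 3, "polarity": "functional"},
  {"scale_id": "impotence", "questionnaire": "CR29", "items": [57], "range": 3, "polarity": "symptom"},
  {"scale_id": "dyspareunia", "questionnaire": "CR29", "items": [59], "range": 3, "polarity": "symptom"}
]
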