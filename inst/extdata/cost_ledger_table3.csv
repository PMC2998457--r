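category,amount_usd,attribution
administration_listing,2766,made_in
administration_verification,3195,made_for
salary_field_workers,53260,shared
supplies_and_service_listing,8656,made_in
supplies_and_service_verification,5539,made_for
travel_listing,45147,made_in
travel_verification,32966,made_for
capital_expenditures,2745,shared
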