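timestamp,location-long,location-lat,individual-local-identifier,fix-status
2022-05-16 02:30:00,,,2201,invalid
2022-05-16 02:40:00,-98.599698606,20.437743462,2201,valid
2022-05-16 02:50:00,,,2201,invalid
2022-05-16 03:00:00,-98.599673183,20.512432073,2201,valid
2022-05-16 03:10:00,-98.600109388,20.523741742,2201,valid
2022-05-16 03:20:00,-98.599999979,20.524171051,2201,valid
2022-05-16 03:30:00,-98.599575129,20.523714005,2201,valid
2022-05-16 03:40:00,-98.599716544,20.524978793,2201,valid
2022-05-16 03:50:00,-98.597796078,20.523380022,2201,valid
2022-05-16 04:00:00,,,2201,invalid
2022-05-16 04:10:00,-98.599365495,20.523504228,2201,valid
2022-05-16 04:20:00,-98.598925950,20.524338607,2201,valid
2022-05-16 04:30:00,-98.598894588,20.523299572,2201,valid
2022-05-16 04:40:00,-98.599231693,20.524322684,2201,valid
2022-05-16 04:50:00,-98.600249407,20.524350638,2201,valid
2022-05-16 05:00:00,,,2201,invalid
2022-05-16 05:10:00,-98.599646139,20.524368143,2201,valid
2022-05-16 05:20:00,-98.599086577,20.526065802,2201,valid
2022-05-16 05:30:00,-98.598975365,20.516431562,2201,valid
2022-05-16 05:40:00,-98.599412021,20.477847182,2201,valid
2022-05-16 05:50:00,,,2201,invalid
2022-05-16 06:00:00,-98.599884872,20.403307094,2201,valid
2022-05-16 06:10:00,,,2201,invalid
2022-05-16 06:20:00,,,2201,invalid
2022-05-16 06:30:00,,,2201,invalid
2022-05-16 06:40:00,-98.597382594,20.408422286,2201,valid
2022-05-16 06:50:00,,,2201,invalid
2022-05-16 07:00:00,-98.575000993,20.479701334,2201,valid
2022-05-16 07:10:00,,,2201,invalid
2022-05-16 07:20:00,-98.552317130,20.552059157,2201,valid
2022-05-16 07:30:00,-98.551806525,20.550217233,2201,valid
2022-05-16 07:40:00,-98.551661196,20.550234621,2201,valid
2022-05-16 07:50:00,-98.553156223,20.551365806,2201,valid
2022-05-16 08:00:00,-98.557951055,20.537450292,2201,valid
2022-05-16 08:10:00,,,2201,invalid
2022-05-16 08:20:00,-98.579925023,20.464825964,2201,valid
2022-05-16 08:30:00,,,2201,invalid
2022-05-16 08:40:00,,,2201,invalid
2022-05-16 08:50:00,,,2201,invalid
2022-05-16 09:00:00,,,2201,invalid
2022-05-16 09:10:00,,,2201,invalid
2022-05-16 09:20:00,,,2201,invalid
2022-05-16 09:30:00,,,2201,invalid
2022-05-16 09:40:00,,,2201,invalid
2022-05-16 09:50:00,,,2201,invalid
2022-05-16 10:00:00,,,2201,invalid
2022-05-16 10:10:00,,,2201,invalid
2022-05-16 10:20:00,,,2201,invalid
2022-05-16 10:30:00,,,2201,invalid
2022-05-16 10:40:00,,,2201,invalid
2022-05-16 10:50:00,,,2201,invalid
2022-05-16 11:00:00,,,2201,invalid
2022-05-16 11:10:00,,,2201,invalid
2022-05-16 11:20:00,,,2201,invalid
2022-05-16 11:30:00,,,2201,invalid
2022-05-16 02:00:00,,,2102,invalid
2022-05-16 02:15:00,-98.608423282,20.455581669,2102,valid
2022-05-16 02:30:00,,,2102,invalid
2022-05-16 02:45:00,,,2102,invalid
2022-05-16 03:00:00,,,2102,invalid
2022-05-16 03:15:00,-98.627324403,20.577218966,2102,valid
2022-05-16 03:30:00,-98.626465118,20.578036306,2102,valid
2022-05-16 03:45:00,-98.626134031,20.578518860,2102,valid
2022-05-16 04:00:00,-98.627293506,20.579959275,2102,valid
2022-05-16 04:15:00,-98.629091211,20.580906887,2102,valid
2022-05-16 04:30:00,,,2102,invalid
2022-05-16 04:45:00,-98.631976838,20.580990350,2102,valid
2022-05-16 05:00:00,,,2102,invalid
2022-05-16 05:15:00,-98.630228893,20.582140624,2102,valid
2022-05-16 05:30:00,-98.631446782,20.583067458,2102,valid
2022-05-16 05:45:00,,,2102,invalid
2022-05-16 06:00:00,-98.630691926,20.581695511,2102,valid
2022-05-16 06:15:00,,,2102,invalid
2022-05-16 06:30:00,-98.630066657,20.581237764,2102,valid
2022-05-16 06:45:00,,,2102,invalid
2022-05-16 07:00:00,-98.629929707,20.582627965,2102,valid
2022-05-16 07:15:00,-98.621511435,20.531550631,2102,valid
2022-05-16 07:30:00,-98.612316083,20.475780591,2102,valid
2022-05-16 07:45:00,,,2102,invalid
2022-05-16 08:00:00,,,2102,invalid
2022-05-16 08:15:00,,,2102,invalid
2022-05-16 08:30:00,,,2102,invalid
2022-05-16 08:45:00,,,2102,invalid
2022-05-16 09:00:00,,,2102,invalid
2022-05-16 09:15:00,,,2102,invalid
2022-05-16 09:30:00,,,2102,invalid
2022-05-16 09:45:00,,,2102,invalid
2022-05-16 10:00:00,,,2102,invalid
2022-05-16 10:15:00,,,2102,invalid
2022-05-16 10:30:00,,,2102,invalid
2022-05-16 10:45:00,,,2102,invalid
2022-05-16 11:00:00,,,2102,invalid
2022-05-16 11:15:00,,,2102,invalid
2022-05-16 11:30:00,,,2102,invalid
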