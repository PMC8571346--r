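component,deaths_thousand,scope
crop_export,25,global sectoral component
livestock_export,36,global sectoral component
china,26.3,country
india,6.2,country
southeast_asia,2.0,regional total
bangladesh,0.9,within southeast_asia
vietnam,0.7,within southeast_asia
pakistan,0.9,country
usa,2.1,country
eastern_europe,9.7,regional total
western_europe,3.9,regional total
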