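# Example domain lexicon: terms characteristic of elderly-care records,
# one per line. Synthetic illustrative subset, not the curated full list.
病院
リハビリテーション
不安
感染
発熱
排尿
排便
吐き気
眼圧
緑内障
白内障
点眼薬
痛み止め
看護師
介護者
バイタル
血圧
脈拍
食事
服薬
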